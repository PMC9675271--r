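chrom	length	centromere_start	centromere_end
chr1	100000000	45000000	51000000
chr2	120000000	55000000	61000000
chr3	90000000	40000000	46000000
chr4	110000000	50000000	56000000
chr5	80000000	35000000	41000000
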