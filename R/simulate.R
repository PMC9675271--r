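#' Simulate a segment profile with planted scar counts
#'
#' Builds a profile whose scar scores are exact by construction:
#' `scar_scores()` on the result returns precisely `(k_loh, k_tai,
#' k_lst)`. The background is balanced 1+1 everywhere; planted events are
#' packed along chromosome arms from the telomere inward as blocks
#' separated by short (4-8 Mb) balanced spacers, engineered so no event
#' leaks into another score:
#'
#' * a **TAI** event is an allelic-imbalance (2+1) segment touching the
#'   telomere (one per arm at most); its inner breakpoint abuts a
#'   sub-10 Mb spacer, so it never counts as an LST;
#' * an **LOH** event is an interstitial `minor_cn = 0` segment of
#'   16-18 Mb (alternating 2+0 / 1+0 states so neighbors never merge),
#'   always preceded by a spacer so it does not touch a telomere;
#' * an **LST** event is a pair of long (>= 10.5 Mb) balanced segments
#'   (2+2 then 3+3) whose internal breakpoint has two long flanks;
#'   balanced states add neither TAI nor LOH.
#'
#' The innermost block of a used arm is stretched to the centromere
#' boundary, so its inner breakpoint falls in the centromere interval and
#' is excluded from LST counting. Events are shuffled over arms under the
#' seed; if the requested counts cannot be packed the function errors.
#'
#' @param genome A `genome_model`; centromeres must be >= 3 Mb wide (so
#'   spacers survive smoothing).
#' @param k_loh,k_tai,k_lst Planted event counts.
#' @param seed RNG seed.
#' @param sample_id Sample name for the generated profile.
#' @return List with `profile` (a `segment_profile`) and `truth`
#'   (`k_loh`, `k_tai`, `k_lst`).
#' @export
simulate_scar_profile <- function(genome, k_loh, k_tai, k_lst, seed,
                                  sample_id = "sim") {
  stop_if_not(k_loh >= 0 && k_tai >= 0 && k_lst >= 0,
              "event counts must be nonnegative")
  stop_if_not(all(genome$centromere_end - genome$centromere_start >= 3e6),
              "centromere intervals must be at least 3 Mb wide")
  arms <- data.frame(
    chrom = rep(genome$chrom, each = 2L),
    side = rep(c("p", "q"), nrow(genome)),
    length = as.vector(rbind(genome$centromere_start,
                             genome$length - genome$centromere_end)),
    stringsAsFactors = FALSE)
  events <- c(rep("tai", k_tai), rep("loh", k_loh), rep("lst", k_lst))
  # worst-case block footprints (jitter stays below these)
  cost <- c(tai = 14e6, loh = 8e6 + 18e6, lst = 8e6 + 2 * 12e6)
  plan <- with_seed(seed, {
    arm_order <- sample.int(nrow(arms))
    ev_order <- sample.int(length(events))
    jit <- list(spacer = stats::runif(length(events), 4e6, 8e6),
                tai_len = stats::runif(length(events), 11e6, 14e6),
                loh_len = stats::runif(length(events), 16e6, 18e6),
                lst_len = matrix(stats::runif(2 * length(events),
                                              10.5e6, 12e6), ncol = 2))
    list(arm_order = arm_order, ev_order = ev_order, jit = jit)
  })
  events <- events[plan$ev_order]
  # greedy first-fit: TAI first (needs a fresh arm telomere)
  events <- events[order(events != "tai")]
  arm_used <- numeric(nrow(arms))     # bp consumed from the telomere
  arm_events <- vector("list", nrow(arms))
  for (i in seq_along(events)) {
    ev <- events[i]
    placed <- FALSE
    for (ai in plan$arm_order) {
      if (ev == "tai" && length(arm_events[[ai]]) > 0L) next
      if (arm_used[ai] + cost[[ev]] > arms$length[ai]) next
      arm_events[[ai]] <- c(arm_events[[ai]], i)
      arm_used[ai] <- arm_used[ai] + cost[[ev]]
      placed <- TRUE
      break
    }
    stop_if_not(placed, "cannot place ", length(events),
                " non-interacting events on this genome (failed at a '",
                ev, "' event)")
  }
  seg_rows <- list()
  for (ci in seq_len(nrow(genome))) {
    chrom <- genome$chrom[ci]
    len <- genome$length[ci]
    cs <- genome$centromere_start[ci]
    ce <- genome$centromere_end[ci]
    for (side in c("p", "q")) {
      ai <- which(arms$chrom == chrom & arms$side == side)
      idxs <- arm_events[[ai]]
      arm_limit <- if (side == "p") cs else len - ce
      pieces <- list()   # (offset_start, offset_end, major, minor), telomere = 0
      pos <- 0
      for (i in idxs) {
        ev <- events[i]
        sp <- plan$jit$spacer[i]
        if (ev == "tai") {
          pieces[[length(pieces) + 1L]] <- c(pos, pos + plan$jit$tai_len[i], 2, 1)
          pos <- pos + plan$jit$tai_len[i]
        } else if (ev == "loh") {
          # alternate 2+0 / 1+0 so consecutive LOH blocks never merge
          major <- if (length(pieces) %% 2L == 0L) 2 else 1
          pieces[[length(pieces) + 1L]] <- c(pos + sp,
                                             pos + sp + plan$jit$loh_len[i],
                                             major, 0)
          pos <- pos + sp + plan$jit$loh_len[i]
        } else {
          l1 <- plan$jit$lst_len[i, 1L]; l2 <- plan$jit$lst_len[i, 2L]
          pieces[[length(pieces) + 1L]] <- c(pos + sp, pos + sp + l1, 2, 2)
          pieces[[length(pieces) + 1L]] <- c(pos + sp + l1,
                                             pos + sp + l1 + l2, 3, 3)
          pos <- pos + sp + l1 + l2
        }
      }
      if (length(pieces) > 0L) {
        # stretch the innermost segment to the centromere boundary
        pieces[[length(pieces)]][2L] <- arm_limit
      }
      # map arm offsets to chromosome coordinates and fill with 1+1
      cursor <- if (side == "p") 0 else len
      for (p in pieces) {
        if (side == "p") {
          if (p[1L] > cursor) {
            seg_rows[[length(seg_rows) + 1L]] <-
              data.frame(chrom = chrom, start = cursor, end = p[1L],
                         major_cn = 1, minor_cn = 1)
          }
          seg_rows[[length(seg_rows) + 1L]] <-
            data.frame(chrom = chrom, start = p[1L], end = p[2L],
                       major_cn = p[3L], minor_cn = p[4L])
          cursor <- p[2L]
        } else {
          s <- len - p[2L]; e <- len - p[1L]
          if (e < cursor) {
            seg_rows[[length(seg_rows) + 1L]] <-
              data.frame(chrom = chrom, start = e, end = cursor,
                         major_cn = 1, minor_cn = 1)
          }
          seg_rows[[length(seg_rows) + 1L]] <-
            data.frame(chrom = chrom, start = s, end = e,
                       major_cn = p[3L], minor_cn = p[4L])
          cursor <- s
        }
      }
      # close the arm down to the centromere with background
      if (side == "p") {
        if (cursor < cs) {
          seg_rows[[length(seg_rows) + 1L]] <-
            data.frame(chrom = chrom, start = cursor, end = cs,
                       major_cn = 1, minor_cn = 1)
        }
      } else {
        if (cursor > ce) {
          seg_rows[[length(seg_rows) + 1L]] <-
            data.frame(chrom = chrom, start = ce, end = cursor,
                       major_cn = 1, minor_cn = 1)
        }
      }
    }
    # centromere filler
    seg_rows[[length(seg_rows) + 1L]] <-
      data.frame(chrom = chrom, start = cs, end = ce,
                 major_cn = 1, minor_cn = 1)
  }
  profile <- segment_profile(sample_id, do.call(rbind, seg_rows), genome)
  list(profile = profile,
       truth = list(k_loh = k_loh, k_tai = k_tai, k_lst = k_lst))
}

#' Simulate a 96-channel catalog from a signature mixture
#'
#' Draws `counts ~ Multinomial(n_mutations, sum_k w_k * signature_k)`.
#'
#' @param dictionary A `signature_dictionary`.
#' @param weights Named (or dictionary-ordered) nonnegative exposure
#'   vector summing to 1 within 1e-6; missing signatures default to 0.
#' @param n_mutations Total mutation count (>= 1).
#' @param seed RNG seed.
#' @param sample_id Sample name.
#' @return A one-row `catalog96`.
#' @export
simulate_catalog <- function(dictionary, weights, n_mutations, seed,
                             sample_id = "sim") {
  stop_if_not(n_mutations >= 1, "n_mutations must be at least 1")
  w <- numeric(nrow(dictionary))
  names(w) <- rownames(dictionary)
  if (is.null(names(weights))) {
    stop_if_not(length(weights) == nrow(dictionary),
                "unnamed weights must match the dictionary length")
    w[] <- weights
  } else {
    unknown <- setdiff(names(weights), names(w))
    stop_if_not(length(unknown) == 0L, "unknown signature(s): ",
                paste(unknown, collapse = ", "))
    w[names(weights)] <- weights
  }
  stop_if_not(all(w >= 0), "weights must be nonnegative")
  stop_if_not(abs(sum(w) - 1) < 1e-6, "weights must sum to 1 (tol 1e-6)")
  p <- as.numeric(crossprod(unclass(dictionary), w))
  counts <- with_seed(seed, as.numeric(stats::rmultinom(1, n_mutations, p)))
  m <- matrix(counts, nrow = 1,
              dimnames = list(sample_id, sbs96_channels()))
  catalog96(m)
}

#' Simulate marker-structured expression with planted abundances
#'
#' Marker gene g of population p in sample s takes the linear value
#' `2^(abundance[s, p] + N(0, noise_sd)) - 1`, floored at 0, so with
#' `noise_sd = 0` the log2(x+1) marker value equals the planted abundance
#' exactly and every panel score recovers it. Background genes are
#' abundance-independent noise: per-gene baseline drawn uniformly on
#' [0, 8] log2 units plus the same per-cell noise. Panels must not share
#' marker genes (overlap would make abundances unidentifiable).
#'
#' @param panels Named list of `gene_set` marker panels (disjoint genes).
#' @param abundances Numeric matrix samples x populations (nonnegative);
#'   column names must match panel names, rownames are sample ids.
#' @param noise_sd Log2-scale Gaussian noise sd.
#' @param n_background_genes Number of abundance-independent genes.
#' @param seed RNG seed.
#' @return An `expression_matrix` (linear scale).
#' @export
simulate_expression <- function(panels, abundances, noise_sd = 0.5,
                                n_background_genes = 100, seed = 1) {
  stop_if_not(all(abundances >= 0), "abundances must be nonnegative")
  all_markers <- unlist(lapply(panels, `[[`, "genes"))
  stop_if_not(!anyDuplicated(all_markers),
              "marker panels must not share genes")
  stop_if_not(!is.null(colnames(abundances)) &&
                setequal(colnames(abundances), names(panels)),
              "abundance columns must match panel names")
  samples <- rownames(abundances) %||% paste0("S", seq_len(nrow(abundances)))
  genes <- c(all_markers,
             if (n_background_genes > 0)
               sprintf("BG%04d", seq_len(n_background_genes)))
  with_seed(seed, {
    m <- matrix(0, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
    for (pn in names(panels)) {
      for (g in panels[[pn]]$genes) {
        mu <- abundances[, pn]
        m[g, ] <- pmax(2^(mu + stats::rnorm(length(mu), 0, noise_sd)) - 1, 0)
      }
    }
    if (n_background_genes > 0) {
      base <- stats::runif(n_background_genes, 0, 8)
      for (i in seq_len(n_background_genes)) {
        g <- sprintf("BG%04d", i)
        m[g, ] <- pmax(2^(base[i] +
                            stats::rnorm(length(samples), 0, noise_sd)) - 1, 0)
      }
    }
    expression_matrix(m)
  })
}

#' Simulate proportional-hazards survival times
#'
#' Event times are exponential with rate
#' `baseline_rate * exp(x' beta)` (the simplest model satisfying
#' proportional hazards); independent exponential censoring with rate
#' `censor_rate` (0 means no censoring). Recorded time is the minimum,
#' the event indicator marks whether the event came first.
#'
#' @param covariates Data frame/matrix of numeric covariates.
#' @param beta Coefficient vector (named or covariate-ordered).
#' @param baseline_rate Events per month (> 0).
#' @param censor_rate Censoring events per month (>= 0).
#' @param seed RNG seed.
#' @return Data frame with `time`, `event`.
#' @export
simulate_survival <- function(covariates, beta, baseline_rate = 0.05,
                              censor_rate = 0.02, seed = 1) {
  stop_if_not(baseline_rate > 0, "baseline_rate must be positive")
  stop_if_not(censor_rate >= 0, "censor_rate must be nonnegative")
  x <- as.matrix(covariates)
  if (!is.null(names(beta)) && !is.null(colnames(x)) &&
      all(colnames(x) %in% names(beta))) {
    beta <- beta[colnames(x)]
  }
  stop_if_not(length(beta) == ncol(x),
              "beta length must match the number of covariates")
  lp <- as.numeric(x %*% beta)
  with_seed(seed, {
    t_event <- stats::rexp(nrow(x), rate = baseline_rate * exp(lp))
    t_cens <- if (censor_rate > 0) {
      stats::rexp(nrow(x), rate = censor_rate)
    } else {
      rep(Inf, nrow(x))
    }
    data.frame(time = pmin(t_event, t_cens),
               event = as.numeric(t_event <= t_cens))
  })
}

#' Default configuration for the synthetic cohort
#'
#' Study-condition defaults for [simulate_cohort()]: a 60-sample cohort
#' with ~15% BRCA-mutated samples and roughly a fifth of the wild-type
#' samples HRD-high (echoing the proportions seen in breast-tumor
#' cohorts); high-tier samples carry 15-25 planted events per scar
#' component (sums well above the 42 cutoff) and low-tier samples 0-3;
#' HRD-high/mutated samples receive Signature-3-dominated mixtures;
#' WT HRD-high samples carry a +2 log2 immune abundance shift; survival
#' follows exponential proportional hazards with a planted TIL-like
#' protective coefficient.
#'
#' @param n Cohort size.
#' @return Config list consumed by [simulate_cohort()].
#' @export
default_cohort_config <- function(n = 60) {
  list(
    n = n,
    proportions = c(BRCA_MUT = 0.15, WT_HRD_HIGH = 0.20, WT_HRD_LOW = 0.65),
    scar_range_high = c(15, 25),       # per component, planted count range
    scar_range_low = c(0, 3),
    hrd_threshold = 42,
    brca_logit = c(intercept = -6, slope = 0.12),
    s3_weight_high = c(0.5, 0.8),      # Signature_3 share for high tier
    s3_weight_low = c(0, 0.1),
    n_mutations = c(2000, 6000),
    immune_shift = 2,                  # log2 units added for WT HRD-high
    abundance_mean = 4, abundance_sd = 0.5,
    noise_sd = 0.3,
    n_background_genes = 60,
    survival_beta = c(TIL_lymphoid_abundance = -0.4),
    baseline_rate = 0.02, censor_rate = 0.01,
    pam50_levels = c("LumA", "LumB", "Her2", "Basal", "normal-like"),
    pam50_probs = c(0.45, 0.25, 0.10, 0.15, 0.05)
  )
}

#' Simulate a complete cohort with planted ground truth
#'
#' End-to-end generator standing in for a downloaded tumor cohort: for
#' each sample it plants scar counts, a signature mixture, cell
#' abundances and a survival linear predictor, then materializes segment
#' profiles, mutation catalogs, an expression matrix and a clinical
#' table. The BRCA-mutated flag is assigned by weighted sampling without
#' replacement with logistic weights in the planted HRD sum
#' (`plogis(intercept + slope * hrd)`), reproducing the association
#' between mutation status and scar burden; intended group labels
#' (mutated / WT HRD-high / WT HRD-low) are stored in the truth table
#' and are exactly recoverable from the planted counts.
#'
#' @param config Config list, see [default_cohort_config()]; group
#'   proportions must sum to 1.
#' @param seed Master RNG seed.
#' @param genome A `genome_model` (default [hg19_like_genome()]; the
#'   genome must be large enough to host the planted event counts).
#' @param dictionary A `signature_dictionary` (default the synthetic
#'   five-signature dictionary).
#' @param panels Marker panels used for the expression layer (default
#'   TIL component panels plus two metagene-like panels).
#' @return List with `profiles`, `catalogs`, `expression`, `clinical`,
#'   `truth` (per-sample planted values incl. `intended_group`), and the
#'   `config`/`genome`/`dictionary`/`panels` used. `n = 0` gives an
#'   empty bundle.
#' @export
simulate_cohort <- function(config = default_cohort_config(), seed = 1,
                            genome = hg19_like_genome(),
                            dictionary = synthetic_signature_dictionary(),
                            panels = NULL) {
  stop_if_not(abs(sum(config$proportions) - 1) < 1e-8,
              "group proportions must sum to 1")
  n <- config$n
  if (is.null(panels)) {
    all_p <- default_marker_panels()
    panels <- all_p[c("TIL_lymphoid", "TIL_myeloid", "TIL_stromal",
                      "TIL_cancer", "IFN_gamma", "CTL")]
    names(panels) <- paste0(names(panels), "_abundance")
    for (i in seq_along(panels)) panels[[i]]$name <- names(panels)[i]
  }
  if (n == 0L) {
    return(list(profiles = list(), catalogs = NULL, expression = NULL,
                clinical = NULL, truth = NULL, config = config,
                genome = genome, dictionary = dictionary, panels = panels))
  }
  ids <- sprintf("S%03d", seq_len(n))
  thr <- config$hrd_threshold

  draws <- with_seed(seed, {
    tier_p_high <- config$proportions[["BRCA_MUT"]] +
      config$proportions[["WT_HRD_HIGH"]]
    tier <- ifelse(stats::runif(n) < tier_p_high, "high", "low")
    k <- matrix(0L, nrow = n, ncol = 3,
                dimnames = list(ids, c("k_loh", "k_tai", "k_lst")))
    for (j in 1:3) {
      rng_hi <- config$scar_range_high
      rng_lo <- config$scar_range_low
      k[, j] <- ifelse(tier == "high",
                       sample(seq(rng_hi[1], rng_hi[2]), n, replace = TRUE),
                       sample(seq(rng_lo[1], rng_lo[2]), n, replace = TRUE))
    }
    hrd <- rowSums(k)
    # BRCA flag: weighted sampling, logistic weights in the planted sum
    n_mut <- round(n * config$proportions[["BRCA_MUT"]])
    wts <- stats::plogis(config$brca_logit[["intercept"]] +
                           config$brca_logit[["slope"]] * hrd)
    mut_idx <- if (n_mut > 0) sample.int(n, n_mut, prob = wts) else integer()
    s3 <- ifelse(hrd > thr,
                 stats::runif(n, config$s3_weight_high[1],
                              config$s3_weight_high[2]),
                 stats::runif(n, config$s3_weight_low[1],
                              config$s3_weight_low[2]))
    nmut96 <- sample(seq(config$n_mutations[1], config$n_mutations[2]),
                     n, replace = TRUE)
    list(tier = tier, k = k, hrd = hrd, mut_idx = mut_idx, s3 = s3,
         nmut96 = nmut96)
  })
  brca <- rep("WT", n)
  brca[draws$mut_idx] <- "mutated"
  intended <- ifelse(brca == "mutated", "BRCA_MUT",
                     ifelse(draws$hrd > thr, "WT_HRD_HIGH", "WT_HRD_LOW"))

  profiles <- lapply(seq_len(n), function(i) {
    simulate_scar_profile(genome, draws$k[i, 1], draws$k[i, 2],
                          draws$k[i, 3], seed = derive_seed(seed, 1000 + i),
                          sample_id = ids[i])$profile
  })
  names(profiles) <- ids

  other_sigs <- setdiff(rownames(dictionary), "Signature_3")
  sig_w <- with_seed(derive_seed(seed, 2), {
    w <- matrix(0, nrow = n, ncol = nrow(dictionary),
                dimnames = list(ids, rownames(dictionary)))
    for (i in seq_len(n)) {
      rest <- stats::runif(length(other_sigs))
      rest <- rest / sum(rest) * (1 - draws$s3[i])
      w[i, "Signature_3"] <- draws$s3[i]
      w[i, other_sigs] <- rest
    }
    w
  })
  catalogs <- do.call(rbind, lapply(seq_len(n), function(i) {
    unclass(simulate_catalog(dictionary, sig_w[i, ], draws$nmut96[i],
                             seed = derive_seed(seed, 2000 + i),
                             sample_id = ids[i]))
  }))
  rownames(catalogs) <- ids
  catalogs <- catalog96(catalogs)

  abund <- with_seed(derive_seed(seed, 3), {
    a <- matrix(stats::rnorm(n * length(panels), config$abundance_mean,
                             config$abundance_sd),
                nrow = n, dimnames = list(ids, names(panels)))
    immune_cols <- intersect(c("TIL_lymphoid_abundance",
                               "TIL_myeloid_abundance",
                               "IFN_gamma_abundance", "CTL_abundance"),
                             colnames(a))
    a[intended == "WT_HRD_HIGH", immune_cols] <-
      a[intended == "WT_HRD_HIGH", immune_cols] + config$immune_shift
    pmax(a, 0)
  })
  expr <- simulate_expression(panels, abund, noise_sd = config$noise_sd,
                              n_background_genes = config$n_background_genes,
                              seed = derive_seed(seed, 4))

  surv_cov <- abund[, names(config$survival_beta), drop = FALSE]
  lp <- as.numeric(surv_cov %*% config$survival_beta)
  os <- simulate_survival(surv_cov, config$survival_beta,
                          baseline_rate = config$baseline_rate,
                          censor_rate = config$censor_rate,
                          seed = derive_seed(seed, 5))
  pfi <- simulate_survival(surv_cov, config$survival_beta,
                           baseline_rate = config$baseline_rate * 1.5,
                           censor_rate = config$censor_rate,
                           seed = derive_seed(seed, 6))
  clin_extra <- with_seed(derive_seed(seed, 7), {
    data.frame(
      pam50 = sample(config$pam50_levels, n, replace = TRUE,
                     prob = config$pam50_probs),
      subtype = "ER+/HER2-",
      t_stage = sample(c("T1", "T2", "T3"), n, replace = TRUE),
      n_stage = sample(c("N0", "N1"), n, replace = TRUE),
      tmb = round(stats::rlnorm(n, log(100), 0.8)),
      stringsAsFactors = FALSE)
  })
  clinical <- clinical_table(data.frame(
    sample_id = ids, brca_status = brca, clin_extra,
    os_time = os$time, os_event = os$event,
    pfi_time = pfi$time, pfi_event = pfi$event,
    stringsAsFactors = FALSE))

  truth <- data.frame(sample_id = ids,
                      k_loh = draws$k[, 1], k_tai = draws$k[, 2],
                      k_lst = draws$k[, 3], hrd_sum = draws$hrd,
                      s3_weight = draws$s3,
                      brca_status = brca, intended_group = intended,
                      linear_predictor = lp,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(abund))

  list(profiles = profiles, catalogs = catalogs, expression = expr,
       clinical = clinical, truth = truth, signature_weights = sig_w,
       config = config, genome = genome, dictionary = dictionary,
       panels = panels)
}
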