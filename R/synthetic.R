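# Synthetic cohort generator: plants purities, clonal structure, signatures,
# arm-level SCNAs, prognostic subtypes and survival times, and returns the
# ground truth alongside the emitted tables.

#' Synthetic chromosome-arm definitions
#'
#' A 22-chromosome genome with p and q arms; coordinates are in megabases,
#' with approximate human chromosome lengths and a centromere at 40% of the
#' chromosome (15% for the acrocentric chromosomes 13, 14, 15, 21, 22).
#'
#' @return Tibble: `arm_id, chromosome, start, end`.
#' @export
synthetic_arm_definitions <- function() {
  lengths <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135,
               134, 115, 107, 102, 90, 81, 78, 59, 63, 48, 51)
  acro <- c(13, 14, 15, 21, 22)
  purrr::map_dfr(seq_along(lengths), function(i) {
    cen <- round(lengths[i] * if (i %in% acro) 0.15 else 0.40)
    tibble(
      arm_id = paste0(i, c("p", "q")),
      chromosome = as.character(i),
      start = c(1, cen + 1),
      end = c(cen, lengths[i])
    )
  })
}

#' Example planted mutational signatures
#'
#' Three well-separated 96-channel signatures used as generator defaults: a
#' CpG deamination-like process (C>T at NpCpG), an aristolochic-acid-like
#' process (T>A at CpTpA and CpTpG), and a broad T>C-biased background process.
#'
#' @return 96 x 3 column-stochastic matrix with channel rownames.
#' @export
example_signatures <- function() {
  ch <- sig_channels()
  cpg <- numeric(96)
  cpg[grepl("\\[C>T\\]G$", ch)] <- 0.85 / 4
  other_ct <- grepl("\\[C>T\\]", ch) & !grepl("\\[C>T\\]G$", ch)
  cpg[other_ct] <- 0.15 / sum(other_ct)
  aa <- rep(0.10 / 96, 96)
  aa[ch %in% c("C[T>A]A", "C[T>A]G")] <- aa[ch %in% c("C[T>A]A", "C[T>A]G")] + 0.60 / 2
  other_ta <- grepl("\\[T>A\\]", ch) & !(ch %in% c("C[T>A]A", "C[T>A]G"))
  aa[other_ta] <- aa[other_ta] + 0.30 / sum(other_ta)
  broad <- rep(0.5 / 96, 96)
  tc <- grepl("\\[T>C\\]", ch)
  broad[tc] <- broad[tc] + 0.5 / sum(tc)
  m <- cbind(CpG = cpg, AA = aa, Broad = broad)
  rownames(m) <- ch
  m
}

#' Default planted driver events
#'
#' Genes and arm-level SCNAs with cohort frequencies and timing classes
#' echoing a clear cell renal cell carcinoma-like genome: an early 3p
#' deletion with early VHL/PBRM1 mutations, intermediate 14q deletion and
#' other SCNAs, and late aneuploidies.
#'
#' @return Tibble: `event_id, kind` (`gene`, `arm_amp`, `arm_del`), `gene,
#'   arm, chromosome, position, frequency, timing`.
#' @export
synthetic_driver_events <- function() {
  tibble::tribble(
    ~event_id,   ~kind,     ~gene,    ~arm,  ~position, ~frequency, ~timing,
    "del(3p)",   "arm_del", NA,       "3p",  NA,        0.85,       "early",
    "VHL",       "gene",    "VHL",    "3p",  10,        0.55,       "early",
    "PBRM1",     "gene",    "PBRM1",  "3p",  53,        0.35,       "early",
    "amp(5q)",   "arm_amp", NA,       "5q",  NA,        0.45,       "early",
    "del(14q)",  "arm_del", NA,       "14q", NA,        0.40,       "intermediate",
    "amp(7p)",   "arm_amp", NA,       "7p",  NA,        0.30,       "intermediate",
    "del(1p)",   "arm_del", NA,       "1p",  NA,        0.18,       "intermediate",
    "del(6q)",   "arm_del", NA,       "6q",  NA,        0.15,       "intermediate",
    "SETD2",     "gene",    "SETD2",  "3p",  47,        0.12,       "intermediate",
    "BAP1",      "gene",    "BAP1",   "3p",  52,        0.12,       "intermediate",
    "del(9p)",   "arm_del", NA,       "9p",  NA,        0.20,       "late",
    "amp(12p)",  "arm_amp", NA,       "12p", NA,        0.15,       "late",
    "del(10q)",  "arm_del", NA,       "10q", NA,        0.15,       "late"
  )
}

#' Default planted prognostic subtypes
#'
#' Three clusters with distinct event-enrichment profiles and hazard
#' multipliers: a long-lived VHL-enriched, SCNA-depleted cluster B and two
#' short-lived SCNA-enriched clusters A and C.
#'
#' @return Tibble: `cluster, proportion, hazard_multiplier, enrichment`
#'   (list-column of named frequency multipliers).
#' @export
synthetic_subtypes <- function() {
  tibble(
    cluster = c("A", "B", "C"),
    proportion = c(0.30, 0.40, 0.30),
    hazard_multiplier = c(2.7, 1.0, 2.7),
    enrichment = list(
      c("amp(12p)" = 3.0, "del(9p)" = 2.5, "del(14q)" = 1.6, "BAP1" = 2.0),
      c("VHL" = 1.7, "BAP1" = 0.15, "del(14q)" = 0.5, "del(9p)" = 0.4,
        "amp(12p)" = 0.3, "del(1p)" = 0.4, "del(10q)" = 0.4, "del(6q)" = 0.5),
      c("del(1p)" = 2.5, "del(10q)" = 2.5, "del(6q)" = 2.0, "del(14q)" = 1.6)
    )
  )
}

#' Synthetic immune gene sets
#'
#' Placeholder gene sets (Th17, Th2, Treg, CD8, APM, Angiogenesis) with
#' synthetic member genes (`IMM_*`). These stand in for published immune
#' signature collections, which users should supply for real analyses.
#'
#' @param set_size Genes per set (default 15).
#' @return Named list of character vectors.
#' @export
synthetic_immune_sets <- function(set_size = 15) {
  sets <- c("Th17", "Th2", "Treg", "CD8", "APM", "Angiogenesis")
  setNames(lapply(sets, function(s) {
    sprintf("IMM_%s_%02d", toupper(s), seq_len(set_size))
  }), sets)
}

# Per-cluster additive log-expression shifts on the immune sets.
subtype_expression_shifts <- function() {
  list(
    A = c(Th2 = 1.0, Treg = 1.0),
    B = c(Th17 = 1.2, CD8 = 1.2),
    C = c(Th2 = 1.2, Treg = 1.2, APM = -1.2, Angiogenesis = -1.0)
  )
}

#' Cohort generator configuration
#'
#' Bundles and validates every knob of [generate_cohort()]. Defaults emulate a
#' renal clear-cell-like cohort: purity 0.3-0.9, ~80 coding SNVs per sample at
#' 100x mean depth, 68% clonal mutations, three planted signatures, thirteen
#' planted drivers and three prognostic subtypes.
#'
#' @param n_samples Number of samples.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param purity_range Uniform sampling interval for tumor purity, within
#'   (0, 1].
#' @param mean_mutations_per_sample Poisson mean of passenger SNVs per sample.
#' @param clonal_fraction Fraction of passenger SNVs planted at CCF 1; also
#'   scales driver subclonality (at 1, no subclonal mutation is planted).
#' @param subclone_ccf_range Uniform CCF interval for subclonal events,
#'   within (0, 1).
#' @param planted_signatures 96 x S column-stochastic signature matrix.
#' @param signature_weights Nonnegative per-cohort mixture weights (sum 1).
#' @param driver_events Tibble as [synthetic_driver_events()].
#' @param subtypes Tibble as [synthetic_subtypes()].
#' @param sequencing_depth Mean tumor sequencing depth (Poisson).
#' @param normal_depth Mean germline depth.
#' @param base_hazard Baseline exponential hazard (per month).
#' @param censor_range Uniform interval (months) for censoring times.
#' @param error_rate Germline/sequencing error rate for normal alt reads.
#' @param signature_dispersion Dirichlet concentration scaling for the
#'   per-sample signature mixture weights (per-sample weights are drawn from
#'   Dirichlet(`signature_dispersion * signature_weights`); smaller values
#'   give stronger inter-patient variation in signature activity).
#' @param arm_coverage Fraction of an arm covered by a planted arm event.
#' @param passenger_scna_rate Per-arm probability of a small passenger
#'   segment (too short to yield an arm-level call).
#' @param silent_fraction Fraction of passenger SNVs that are silent.
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_samples = 200,
                          seed = 1,
                          purity_range = c(0.3, 0.9),
                          mean_mutations_per_sample = 80,
                          clonal_fraction = 0.68,
                          subclone_ccf_range = c(0.1, 0.6),
                          planted_signatures = example_signatures(),
                          signature_weights = c(CpG = 0.4, AA = 0.25, Broad = 0.35),
                          driver_events = synthetic_driver_events(),
                          subtypes = synthetic_subtypes(),
                          sequencing_depth = 100,
                          normal_depth = 60,
                          base_hazard = log(2) / 60,
                          censor_range = c(12, 140),
                          error_rate = 1e-3,
                          signature_dispersion = 2,
                          arm_coverage = 0.9,
                          passenger_scna_rate = 0.03,
                          silent_fraction = 0.25) {
  cfg <- list(
    n_samples = as.integer(n_samples), seed = as.integer(seed),
    purity_range = purity_range,
    mean_mutations_per_sample = mean_mutations_per_sample,
    clonal_fraction = clonal_fraction,
    subclone_ccf_range = subclone_ccf_range,
    planted_signatures = as.matrix(planted_signatures),
    signature_weights = signature_weights,
    driver_events = driver_events, subtypes = subtypes,
    sequencing_depth = sequencing_depth, normal_depth = normal_depth,
    base_hazard = base_hazard, censor_range = censor_range,
    error_rate = error_rate, signature_dispersion = signature_dispersion,
    arm_coverage = arm_coverage,
    passenger_scna_rate = passenger_scna_rate,
    silent_fraction = silent_fraction
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_samples < 1) abort("n_samples must be >= 1")
  check_range(cfg$purity_range, 0, 1, "purity_range", lo_open = TRUE)
  check_range(cfg$clonal_fraction, 0, 1, "clonal_fraction")
  check_range(cfg$subclone_ccf_range, 0, 1, "subclone_ccf_range",
              lo_open = TRUE, hi_open = TRUE)
  if (cfg$mean_mutations_per_sample <= 0) abort("mean_mutations_per_sample must be positive")
  if (cfg$sequencing_depth < 1) abort("sequencing_depth must be >= 1")
  sig <- cfg$planted_signatures
  if (nrow(sig) != 96) abort("planted_signatures must have 96 rows")
  if (any(sig < 0)) abort("planted signature vectors must be nonnegative")
  if (any(abs(colSums(sig) - 1) > 1e-6)) abort("planted signature columns must sum to 1")
  w <- cfg$signature_weights
  if (length(w) != ncol(sig)) abort("one signature weight per planted signature required")
  if (any(w < 0)) abort("signature weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-6) abort("signature weights must sum to 1")
  ev <- cfg$driver_events
  if (nrow(ev) > 0) {
    if (any(ev$frequency <= 0 | ev$frequency > 1)) {
      abort("driver frequencies must be in (0, 1]")
    }
    if (!all(ev$timing %in% c("early", "intermediate", "late"))) {
      abort("driver timing must be early/intermediate/late")
    }
    if (anyDuplicated(ev$event_id)) abort("duplicate driver event ids")
    rank <- c(early = 1, intermediate = 2, late = 3)[ev$timing]
    for (i in seq_len(nrow(ev))) {
      later <- ev$frequency[rank > rank[i]]
      if (length(later) > 0 &&
          cfg$n_samples * ev$frequency[i] * sum(later) < 0.5) {
        abort(sprintf(
          "infeasible config: expected co-occurrence of '%s' with later events is below one sample",
          ev$event_id[i]))
      }
    }
  }
  st <- cfg$subtypes
  if (abs(sum(st$proportion) - 1) > 1e-6) abort("subtype proportions must sum to 1")
  if (any(st$hazard_multiplier <= 0)) abort("hazard multipliers must be positive")
  invisible(cfg)
}

# Channel draws from the planted signature mixture; returns the signature of
# origin alongside each channel label.
draw_signature_channels <- function(signatures, weights, n) {
  if (n == 0) {
    return(tibble(signature = character(), channel = character()))
  }
  sig_names <- colnames(signatures) %||% paste0("P", seq_len(ncol(signatures)))
  comp <- sample(seq_len(ncol(signatures)), n, replace = TRUE, prob = weights)
  ch <- vapply(comp, function(s) {
    sample(rownames(signatures), 1, prob = signatures[, s])
  }, character(1))
  tibble(signature = sig_names[comp], channel = ch)
}

#' Draw trinucleotide contexts from planted signatures
#'
#' @param signatures 96 x S column-stochastic matrix with channel rownames.
#' @param weights Mixture weights (nonnegative, summing to 1).
#' @param n Number of mutations to draw.
#' @return Character vector of `n` channel labels.
#' @export
plant_signature_mutations <- function(signatures, weights, n) {
  signatures <- as.matrix(signatures)
  if (is.null(rownames(signatures))) rownames(signatures) <- sig_channels()
  if (any(weights < 0)) abort("signature weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-6) abort("signature weights must sum to 1")
  draw_signature_channels(signatures, weights, n)$channel
}

# Subclonality probability per timing class, scaled so that clonal_fraction 1
# plants no subclonal event at all.
timing_subclonal_prob <- function(timing, clonal_fraction) {
  w <- c(early = 0.15, intermediate = 1.56, late = 2.875)
  pmin(1, w[timing] * (1 - clonal_fraction))
}

TIMING_RANK <- c(early = 1, intermediate = 2, late = 3)

#' Generate a synthetic cohort with known ground truth
#'
#' Plants, per sample: a purity, a prognostic subtype, driver events (genes
#' and arm-level SCNAs) with timing-consistent clonality, passenger SNVs with
#' trinucleotide contexts drawn from the planted signature mixture,
#' copy-number segments realizing the arm events, exponential survival times
#' scaled by the subtype hazard multiplier, and an expression matrix with
#' subtype-specific immune gene-set shifts.
#'
#' Read counts are drawn binomially at Poisson depths around
#' `sequencing_depth` with expected VAF
#' `ccf * purity * m / (purity * q_t + (1 - purity) * 2)` (multiplicity 1, and
#' `q_t` from the sample's planted segments). An event is forced clonal
#' whenever a strictly later-timing event co-occurs in the same sample, which
#' realizes the planted temporal order.
#'
#' @param config A [cohort_config()].
#' @return Object of class `"cohort"`: `mutations, segments, purity, arms,
#'   clinical, expression, gene_sets`, the `truth` list (`mutations,
#'   arm_events, samples, events`), and the `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  set.seed(config$seed)

  arms <- synthetic_arm_definitions()
  n <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  st <- config$subtypes
  cluster <- sample(st$cluster, n, replace = TRUE, prob = st$proportion)
  purity <- runif(n, config$purity_range[1], config$purity_range[2])
  hazard_mult <- setNames(st$hazard_multiplier, st$cluster)[cluster]

  ev <- config$driver_events
  enrich <- setNames(st$enrichment, st$cluster)

  # --- driver presence and clonality ------------------------------------
  driver_rows <- purrr::map_dfr(seq_len(n), function(i) {
    if (nrow(ev) == 0) return(tibble())
    mult <- enrich[[cluster[i]]]
    p_present <- pmin(0.95, ev$frequency *
                        ifelse(ev$event_id %in% names(mult),
                               mult[ev$event_id], 1))
    present <- runif(nrow(ev)) < p_present
    if (!any(present)) return(tibble())
    sub <- ev[present, , drop = FALSE]
    p_sub <- timing_subclonal_prob(sub$timing, config$clonal_fraction)
    subclonal <- runif(nrow(sub)) < p_sub
    # enforce the planted temporal order within the sample
    rank <- TIMING_RANK[sub$timing]
    has_later <- vapply(rank, function(r) any(rank > r), logical(1))
    subclonal[has_later] <- FALSE
    ccf <- ifelse(subclonal,
                  runif(nrow(sub), config$subclone_ccf_range[1],
                        config$subclone_ccf_range[2]),
                  1)
    tibble(sample_id = sample_ids[i], event_id = sub$event_id,
           kind = sub$kind, gene = sub$gene, arm = sub$arm,
           position = sub$position, timing = sub$timing,
           ccf = ccf, clonality = ifelse(subclonal, "subclonal", "clonal"))
  })

  # --- segments ----------------------------------------------------------
  arm_truth <- driver_rows %>% filter(.data$kind %in% c("arm_amp", "arm_del"))
  grid <- tidyr::expand_grid(si = seq_len(n), ai = seq_len(nrow(arms)))
  grid$sample_id <- sample_ids[grid$si]
  grid$arm_id <- arms$arm_id[grid$ai]
  grid$chromosome <- arms$chromosome[grid$ai]
  grid$a_start <- arms$start[grid$ai]
  grid$a_end <- arms$end[grid$ai]
  grid$arm_len <- grid$a_end - grid$a_start + 1
  grid <- left_join(
    grid,
    arm_truth %>% select("sample_id", arm_id = "arm", "kind",
                         t_ccf = "ccf", t_clon = "clonality"),
    by = c("sample_id", "arm_id")
  )
  is_drv <- !is.na(grid$kind)
  is_pass <- !is_drv & runif(nrow(grid)) < config$passenger_scna_rate

  seg_parts <- list()
  if (any(is_drv)) {
    d <- grid[is_drv, ]
    cn <- ifelse(d$kind == "arm_amp", 3L, 1L)
    alt_len <- round(d$arm_len * config$arm_coverage)
    bp <- d$a_start + floor(alt_len * runif(nrow(d), 0.3, 0.7))
    obs1 <- ifelse(d$t_clon == "clonal",
                   pmin(1, 1 - abs(rnorm(nrow(d), 0, 0.012))),
                   pmin(0.94, pmax(0.02, d$t_ccf + rnorm(nrow(d), 0, 0.02))))
    obs2 <- ifelse(d$t_clon == "clonal",
                   pmin(1, 1 - abs(rnorm(nrow(d), 0, 0.012))),
                   pmin(0.94, pmax(0.02, d$t_ccf + rnorm(nrow(d), 0, 0.02))))
    seg_parts$driver <- tibble(
      sample_id = rep(d$sample_id, 3),
      chromosome = rep(d$chromosome, 3),
      start = c(d$a_start, bp + 1, d$a_start + alt_len),
      end = c(bp, d$a_start + alt_len - 1, d$a_end),
      total_copy_number = c(cn, cn, rep(2L, nrow(d))),
      segment_ccf = c(obs1, obs2, rep(NA_real_, nrow(d)))
    )
  }
  if (any(is_pass)) {
    p <- grid[is_pass, ]
    len <- pmax(1, round(p$arm_len * runif(nrow(p), 0.05, 0.35)))
    st0 <- p$a_start + floor(runif(nrow(p), 0, p$arm_len - len))
    cn <- sample(c(1L, 3L), nrow(p), replace = TRUE)
    seg_parts$passenger <- tibble(
      sample_id = rep(p$sample_id, 3),
      chromosome = rep(p$chromosome, 3),
      start = c(p$a_start, st0, st0 + len),
      end = c(st0 - 1, st0 + len - 1, p$a_end),
      total_copy_number = c(rep(2L, nrow(p)), cn, rep(2L, nrow(p))),
      segment_ccf = c(rep(NA_real_, nrow(p)), runif(nrow(p), 0.2, 1),
                      rep(NA_real_, nrow(p)))
    ) %>% filter(.data$end >= .data$start)
  }
  neutral <- grid[!is_drv & !is_pass, ]
  seg_parts$neutral <- tibble(
    sample_id = neutral$sample_id, chromosome = neutral$chromosome,
    start = neutral$a_start, end = neutral$a_end,
    total_copy_number = 2L, segment_ccf = NA_real_
  )
  segments <- bind_rows(seg_parts) %>%
    arrange(.data$sample_id, .data$chromosome, .data$start)
  seg_len <- segments$end - segments$start + 1
  ploidy <- vapply(split(seg_len * segments$total_copy_number,
                         segments$sample_id), sum, numeric(1)) /
    vapply(split(seg_len, segments$sample_id), sum, numeric(1))
  ploidy <- ploidy[sample_ids]

  purity_tbl <- tibble(sample_id = sample_ids, purity = purity,
                       ploidy = round(ploidy, 3))

  # --- mutations ----------------------------------------------------------
  gene_drivers <- driver_rows %>% filter(.data$kind == "gene")
  passenger_pool <- sprintf("P%05d", seq_len(20000))
  arm_weights <- (arms$end - arms$start + 1)

  mut_list <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sample_ids[i]
    gd <- gene_drivers %>% filter(.data$sample_id == s)
    n_pass <- rpois(1, config$mean_mutations_per_sample)
    pass_arm <- sample.int(nrow(arms), n_pass, replace = TRUE, prob = arm_weights)
    pass <- tibble(
      gene = sample(passenger_pool, n_pass, replace = TRUE),
      chromosome = arms$chromosome[pass_arm],
      position = floor(runif(n_pass, arms$start[pass_arm], arms$end[pass_arm] + 1)),
      effect = as.character(ifelse(runif(n_pass) < config$silent_fraction,
                                   "silent", "non_silent")),
      timing = NA_character_,
      clonality = as.character(ifelse(runif(n_pass) < config$clonal_fraction,
                                      "clonal", "subclonal"))
    ) %>%
      mutate(ccf = ifelse(.data$clonality == "clonal", 1,
                          runif(n_pass, config$subclone_ccf_range[1],
                                config$subclone_ccf_range[2])))
    drv <- tibble(
      gene = gd$gene,
      chromosome = arms$chromosome[match(gd$arm, arms$arm_id)],
      position = gd$position,
      effect = "non_silent",
      timing = gd$timing,
      clonality = gd$clonality,
      ccf = gd$ccf
    )
    mut <- bind_rows(drv, pass)
    if (nrow(mut) == 0) next
    w_i <- rgamma(length(config$signature_weights),
                  shape = config$signature_dispersion * config$signature_weights)
    if (sum(w_i) == 0) w_i <- config$signature_weights
    ctx <- draw_signature_channels(config$planted_signatures,
                                   w_i / sum(w_i), nrow(mut))
    parsed <- parse_channel(ctx$channel)
    # emit roughly half the records on the purine strand to exercise folding
    flip <- runif(nrow(mut)) < 0.5
    mut <- mut %>%
      mutate(
        sample_id = s,
        signature = ctx$signature,
        ref_allele = ifelse(flip, revcomp_base(parsed$ref), parsed$ref),
        alt_allele = ifelse(flip, revcomp_base(parsed$alt), parsed$alt),
        context_5p = ifelse(flip, revcomp_base(parsed$three_prime), parsed$five_prime),
        context_3p = ifelse(flip, revcomp_base(parsed$five_prime), parsed$three_prime)
      )
    mut_list[[i]] <- mut
  }
  mutations <- bind_rows(mut_list)
  mutations$mutation_id <- sprintf("M%06d", seq_len(nrow(mutations)))

  # read counts from the planted segments' copy number
  q_t <- lookup_q_t(mutations, segments)
  pur <- purity[match(mutations$sample_id, sample_ids)]
  vaf_true <- mutations$ccf * pur / (pur * q_t + (1 - pur) * 2)
  t_depth <- pmax(1L, rpois(nrow(mutations), config$sequencing_depth))
  t_alt <- rbinom(nrow(mutations), t_depth, vaf_true)
  n_depth <- pmax(1L, rpois(nrow(mutations), config$normal_depth))
  n_alt <- rbinom(nrow(mutations), n_depth, config$error_rate)

  truth_mut <- mutations %>%
    select("mutation_id", "sample_id", "gene", "effect", "timing",
           "signature", "ccf", "clonality")
  mutations <- mutations %>%
    mutate(tumor_alt_count = t_alt, tumor_depth = t_depth,
           normal_alt_count = n_alt, normal_depth = n_depth) %>%
    mutate(position = as.integer(.data$position)) %>%
    select("mutation_id", "sample_id", "gene", "chromosome", "position",
           "ref_allele", "alt_allele", "tumor_alt_count", "tumor_depth",
           "normal_alt_count", "normal_depth", "effect",
           "context_5p", "context_3p")

  # --- clinical -----------------------------------------------------------
  rate <- config$base_hazard * hazard_mult
  event_time <- rexp(n, rate)
  censor_time <- runif(n, config$censor_range[1], config$censor_range[2])
  clinical <- tibble(
    sample_id = sample_ids,
    survival_time = round(pmin(event_time, censor_time), 2),
    event_observed = event_time <= censor_time,
    age = round(pmin(90, pmax(30, rnorm(n, 60, 10)))),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.65, 0.35)),
    t_stage = sample(paste0("T", 1:4), n, replace = TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1)),
    fuhrman_grade = sample(paste0("G", 1:4), n, replace = TRUE,
                           prob = c(0.15, 0.35, 0.35, 0.15))
  )

  # --- expression ---------------------------------------------------------
  sets <- synthetic_immune_sets()
  genes <- c(unlist(sets, use.names = FALSE), sprintf("FILLER_%03d", 1:210))
  expr <- matrix(rnorm(length(genes) * n), nrow = length(genes),
                 dimnames = list(genes, sample_ids))
  shifts <- subtype_expression_shifts()
  for (i in seq_len(n)) {
    sh <- shifts[[cluster[i]]]
    if (is.null(sh)) next
    for (set_name in names(sh)) {
      expr[sets[[set_name]], i] <- expr[sets[[set_name]], i] + sh[[set_name]]
    }
  }
  expr <- round(expr, 4)

  truth <- list(
    mutations = truth_mut,
    arm_events = arm_truth %>%
      mutate(direction = if_else(.data$kind == "arm_amp", "amp", "del")) %>%
      select("sample_id", "event_id", "arm_id" = "arm", "direction",
             "timing", "ccf", "clonality"),
    samples = tibble(sample_id = sample_ids, subtype = cluster,
                     purity = purity, hazard_multiplier = unname(hazard_mult)),
    events = select(ev, "event_id", "kind", "frequency", "timing")
  )

  structure(
    list(mutations = mutations, segments = segments, purity = purity_tbl,
         arms = arms, clinical = clinical, expression = expr,
         gene_sets = sets, truth = truth, config = config),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d samples, %d SNVs, %d segments, %d planted arm events\n",
    nrow(x$purity), nrow(x$mutations), nrow(x$segments),
    nrow(x$truth$arm_events)))
  invisible(x)
}

#' Read a cohort configuration from a YAML file
#'
#' The file may override any [cohort_config()] argument; `planted_signatures`
#' is given as a named map of 96-vectors, `driver_events` and `subtypes` as
#' lists of records (subtype `enrichment` as a named map).
#'
#' @param path Path to the YAML file.
#' @return A `"cohort_config"`.
#' @export
read_cohort_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading cohort configurations requires the yaml package")
  }
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$planted_signatures)) {
    m <- do.call(cbind, lapply(raw$planted_signatures, as.numeric))
    rownames(m) <- sig_channels()
    args$planted_signatures <- m
  }
  if (!is.null(raw$signature_weights)) {
    args$signature_weights <- unlist(raw$signature_weights)
  }
  if (!is.null(raw$driver_events)) {
    args$driver_events <- purrr::map_dfr(raw$driver_events, function(r) {
      tibble(event_id = r$event_id, kind = r$kind,
             gene = r$gene %||% NA_character_, arm = r$arm %||% NA_character_,
             position = r$position %||% NA_real_,
             frequency = r$frequency, timing = r$timing)
    })
  }
  if (!is.null(raw$subtypes)) {
    args$subtypes <- tibble(
      cluster = vapply(raw$subtypes, `[[`, character(1), "cluster"),
      proportion = vapply(raw$subtypes, `[[`, numeric(1), "proportion"),
      hazard_multiplier = vapply(raw$subtypes, `[[`, numeric(1), "hazard_multiplier"),
      enrichment = lapply(raw$subtypes, function(r) unlist(r$enrichment))
    )
  }
  do.call(cohort_config, args)
}

#' Planted CCF-profile matrix for subtyping
#'
#' Generates an events-by-samples CCF matrix with `k` planted sample clusters:
#' each cluster carries its own block of events (CCF drawn near 1 for shared
#' clonal events, lower for cluster-specific subclonal profiles), plus sparse
#' background events, emulating the CCF matrix built from prognosis-associated
#' genes and arm-level SCNAs.
#'
#' @param n_samples Number of samples.
#' @param k Number of planted clusters.
#' @param events_per_cluster Cluster-specific events per cluster (default 5).
#' @param shared_events Events present across all clusters (default 2).
#' @param present_prob Probability that a sample carries one of its own
#'   cluster's events (default 0.9).
#' @param background_prob Probability of carrying another cluster's event
#'   (default 0.05).
#' @param seed Optional integer seed.
#' @return List with `matrix` (events x samples) and `truth` (tibble
#'   `sample_id, cluster`).
#' @export
synthetic_ccf_matrix <- function(n_samples = 150, k = 3,
                                 events_per_cluster = 5, shared_events = 2,
                                 present_prob = 0.9, background_prob = 0.05,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  clusters <- LETTERS[seq_len(k)]
  truth <- tibble(
    sample_id = sprintf("S%04d", seq_len(n_samples)),
    cluster = sample(clusters, n_samples, replace = TRUE)
  )
  events <- c(
    if (shared_events > 0) sprintf("shared_%d", seq_len(shared_events)),
    unlist(lapply(clusters, function(cl) {
      sprintf("%s_event_%d", cl, seq_len(events_per_cluster))
    }))
  )
  own <- setNames(lapply(clusters, function(cl) {
    grep(paste0("^", cl, "_event_"), events)
  }), clusters)
  m <- matrix(0, nrow = length(events), ncol = n_samples,
              dimnames = list(events, truth$sample_id))
  for (j in seq_len(n_samples)) {
    cl <- truth$cluster[j]
    if (shared_events > 0) {
      m[seq_len(shared_events), j] <- runif(shared_events, 0.85, 1)
    }
    mine <- own[[cl]]
    hit <- runif(length(mine)) < present_prob
    m[mine[hit], j] <- runif(sum(hit), 0.6, 1)
    others <- setdiff(unlist(own), mine)
    bg <- runif(length(others)) < background_prob
    m[others[bg], j] <- runif(sum(bg), 0.1, 0.6)
  }
  list(matrix = m, truth = truth)
}
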