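# Shared fixtures. Cohorts are generated once per test run and reused.

cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(name, config) {
  if (is.null(cohort_cache[[name]])) {
    cohort_cache[[name]] <- generate_cohort(config)
  }
  cohort_cache[[name]]
}

small_cohort <- function() {
  cached_cohort("small", cohort_config(n_samples = 40, seed = 101))
}

# Independent dense-grid CCF posterior oracle: manual binomial pmf via
# lchoose, normalized by plain summation.
oracle_ccf <- function(alt, depth, purity, q_t, m, grid_size = 100) {
  grid <- seq(0.01, 1, length.out = grid_size)
  vaf <- grid * purity * m / (purity * q_t + (1 - purity) * 2)
  loglik <- lchoose(depth, alt) + alt * log(vaf) + (depth - alt) * log1p(-vaf)
  w <- exp(loglik - max(loglik))
  probs <- w / sum(w)
  list(grid = grid, probs = probs,
       point = min(sum(grid * probs), 1),
       p95 = sum(probs[grid >= 0.95]))
}

# Three-event cohort with a planted linear temporal order A -> B -> C.
abc_driver_events <- function() {
  tibble::tribble(
    ~event_id, ~kind,     ~gene,    ~arm,  ~position, ~frequency, ~timing,
    "A",       "arm_del", NA,       "3p",  NA,        0.9,        "early",
    "B",       "gene",    "GENE_B", "5q",  40,        0.8,        "intermediate",
    "C",       "arm_del", NA,       "14q", NA,        0.7,        "late"
  )
}

neutral_subtypes <- function() {
  st <- synthetic_subtypes()
  st$enrichment <- list(numeric(), numeric(), numeric())
  st
}

# Event-level clonality calls (arms + one gene) for the A/B/C cohort.
abc_event_calls <- function(cohort) {
  arm <- arm_events(cohort$segments, cohort$purity, cohort$arms) |>
    dplyr::filter(clonality != "none") |>
    dplyr::mutate(event_id = dplyr::recode(event_id,
                                           "del(3p)" = "A", "del(14q)" = "C")) |>
    dplyr::filter(event_id %in% c("A", "C")) |>
    dplyr::select(sample_id, event_id, clonality, ccf)
  gene <- snv_clonality(filter_snvs(cohort$mutations), cohort$purity,
                        cohort$segments) |>
    exclude_multihit_genes() |>
    dplyr::filter(gene == "GENE_B") |>
    dplyr::transmute(sample_id, event_id = "B", clonality, ccf)
  dplyr::bind_rows(arm, gene)
}

write_fixture_fasta <- function(path, sequences) {
  lines <- unlist(lapply(names(sequences), function(nm) {
    c(paste0(">", nm), sequences[[nm]])
  }))
  writeLines(lines, path)
  path
}

# Brute-force running-sum oracle, written independently of the implementation:
# walks the ranked gene list step by step and accumulates both CDFs.
oracle_ssgsea <- function(expr_vector, set, alpha) {
  genes <- names(sort(expr_vector, decreasing = TRUE))
  r <- rank(expr_vector)[genes]
  in_set <- genes %in% set
  num <- 0; den <- sum(r[in_set]^alpha)
  miss <- 0; n_out <- sum(!in_set)
  total <- 0
  for (i in seq_along(genes)) {
    if (in_set[i]) num <- num + r[genes[i]]^alpha else miss <- miss + 1
    total <- total + num / den - miss / n_out
  }
  unname(total)
}

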