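# Shared fixtures for the test suite. Small configurations keep module
# tests fast; the acceptance tests use the generator defaults.

tiny_config <- function(...) {
  defaults <- list(n_arms = 4, amplicons_per_arm = 40, n_controls = 40,
                   n_cancers = 30, depth_mean = 5e4)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# hand-written 3-sample x 4-amplicon fixture with its panel
tiny_counts_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  counts <- tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    batch = c("b1", "b1", "b2"),
    ampA = c(10L, 20L, 30L), ampB = c(1L, 2L, 3L),
    ampC = c(5L, 5L, 5L), ampD = c(0L, 7L, 9L)
  )
  panel <- tibble::tibble(
    amplicon_id = c("ampA", "ampB", "ampC", "ampD"),
    chrom = c("1", "1", "2", "2"),
    arm = c("1p", "1p", "2q", "2q"),
    start = c(1000L, 2000L, 3000L, 4000L),
    insert_length = c(90L, 150L, 100L, 140L)
  )
  cp <- file.path(dir, "counts.tsv")
  pp <- file.path(dir, "panel.tsv")
  readr::write_tsv(counts, cp)
  readr::write_tsv(panel, pp)
  list(counts_path = cp, panel_path = pp, counts = counts, panel = panel)
}

v_to_frac <- function(v, arm_of) {
  arms <- sort(unique(arm_of[names(v)]))
  vapply(arms, function(a) sum(v[arm_of[names(v)] == a]) / sum(v), numeric(1))
}

# deterministic small trained fragmentation model, cached per session
cached_env <- new.env(parent = emptyenv())

small_signal_world <- function() {
  if (is.null(cached_env$ssw)) {
    cfg <- sim_config(n_arms = 4, amplicons_per_arm = 120, n_controls = 120,
                      n_cancers = 90)
    sim <- gen_cohort(cfg, seed = 421)
    fit <- suppressWarnings(signal_fit(
      sim$counts, sim$panel, sim$cohort$group == "cancer", k = 2, seed = 422
    ))
    cached_env$ssw <- list(cfg = cfg, sim = sim, fit = fit)
  }
  cached_env$ssw
}
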