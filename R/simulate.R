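# Synthetic-data generators. They emulate the statistical structure the
# assays assume: amplicon count matrices with batch effects, a tumor
# fraction that tilts representation toward short-insert amplicons
# (fragmentation) and multiplies altered arms (aneuploidy); log-normal
# plasma protein panels with case elevations; and binomially partitioned
# mutant templates across the wells of the multi-well assay.

#' Simulation configuration
#'
#' All knobs of the synthetic cohort, protein and well generators with
#' their default study conditions. Counts are negative-binomial
#' (over-dispersed, dispersion 0.1) around per-amplicon propensities. In a
#' sample with tumor fraction `t`, propensities acquire a log-linear
#' fragmentation tilt `exp(-frag_beta * t * (insert_length -
#' min(insert_length)))` so shorter amplicons are over-represented in
#' proportion to tumor burden, and altered arms are multiplied by
#' `1 +/- t / 2`.
#'
#' @param n_arms Number of chromosome arms on the synthetic panel.
#' @param amplicons_per_arm Amplicons per arm.
#' @param insert_range Range (bp) of expected insert lengths, sampled
#'   uniformly. Default 80-160.
#' @param n_controls,n_cancers Cohort sizes.
#' @param tumor_fraction_range Uniform range of the latent tumor fraction
#'   of cancer samples.
#' @param frag_beta Fragmentation tilt strength per bp of insert length.
#' @param n_altered_range Range of the number of aneuploid arms per cancer
#'   sample.
#' @param n_batches Number of sequencing batches (round-robin assignment).
#' @param subject_sd SD of the per-subject log-normal amplicon propensity
#'   jitter (between-subject biological variability; duplicate aliquots of
#'   a sample share it).
#' @param batch_sd SD of per-(batch, amplicon) log-normal multipliers.
#' @param depth_mean Mean total reads per sample.
#' @param dispersion Negative-binomial dispersion (1/size) of counts.
#' @param protein_effect Natural-log fold change applied to the affected
#'   analytes of case samples.
#' @param protein_n_affected How many of the 17 analytes are elevated in
#'   cases.
#' @param protein_sdlog Log-normal SD of analyte baselines.
#' @param wells Number of wells of the partitioned mutation assay.
#' @param genome_equivalents Genome equivalents per well (upper bound of
#'   the assay design).
#' @param well_depth Mean sequencing reads per well.
#' @param error_rate Per-read sequencing/PCR error rate driving background
#'   noise.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_arms = 8, amplicons_per_arm = 240,
                       insert_range = c(80, 160),
                       n_controls = 327, n_cancers = 379,
                       tumor_fraction_range = c(0.02, 0.25),
                       frag_beta = 0.06,
                       n_altered_range = c(1, 3),
                       n_batches = 2, batch_sd = 0.05, subject_sd = 0.25,
                       depth_mean = 2e5, dispersion = 0.1,
                       protein_effect = 1.0, protein_n_affected = 6,
                       protein_sdlog = 0.5,
                       wells = 95, genome_equivalents = 300,
                       well_depth = 3000, error_rate = 1e-4) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_arms >= 1, cfg$amplicons_per_arm >= 2,
            cfg$frag_beta >= 0, cfg$dispersion > 0,
            all(cfg$tumor_fraction_range >= 0),
            all(cfg$tumor_fraction_range <= 1),
            cfg$error_rate >= 0, cfg$error_rate < 1)
  structure(cfg, class = "sim_config")
}

sim_panel <- function(config) {
  arms <- paste0(rep(seq_len(config$n_arms) + 0L, each = 1), rep(c("p", "q"),
                 length.out = config$n_arms))
  arms <- unique(arms)[seq_len(config$n_arms)]
  n <- config$n_arms * config$amplicons_per_arm
  amplicon_panel(tibble::tibble(
    amplicon_id = sprintf("amp%04d", seq_len(n)),
    chrom = rep(sub("[pq]$", "", arms), each = config$amplicons_per_arm),
    arm = rep(arms, each = config$amplicons_per_arm),
    start = seq_len(n) * 1000L,
    insert_length = round(runif(n, config$insert_range[1], config$insert_range[2]))
  ), drop_acrocentric_p = FALSE)
}

#' Generate a synthetic amplicon cohort
#'
#' Draws a panel, latent per-sample truth (tumor fraction, altered arms,
#' batch) and negative-binomial counts. Control samples follow baseline
#' amplicon propensities times batch multipliers; in cancer samples a
#' tumor-derived fraction `t` tilts propensities toward short-insert
#' amplicons (strength `frag_beta`) and multiplies altered arms by
#' `1 +/- t/2`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; output is bit-identical given the seed.
#' @param world A `sim_world` from a previous `gen_cohort()` call (element
#'   `world` of its result): the fixed assay universe (panel, baseline
#'   amplicon propensities, batch multipliers). Supply it to draw new
#'   samples on the *same* panel, e.g. held-out test samples for a model
#'   trained on an earlier cohort. `NULL` creates a fresh world from
#'   `seed`.
#' @param replicate_seed If not `NULL`, a second counts realization of the
#'   same latent samples is returned as `counts_rep` (duplicate-aliquot
#'   mode).
#' @return List with `world`, `panel`, `counts` (a [count_matrix()]),
#'   `cohort` (a `cohort_table` with groups `non_cancer` / `cancer`),
#'   `truth` (per-sample tibble of latent parameters) and optionally
#'   `counts_rep`.
#' @export
gen_cohort <- function(config = sim_config(), seed = 1L, world = NULL,
                       replicate_seed = NULL) {
  set.seed(seed)
  if (is.null(world)) {
    panel <- sim_panel(config)
    n_amp <- nrow(panel)
    base_p <- exp(rnorm(n_amp, 0, 0.4))
    base_p <- base_p / sum(base_p)
    batch_mult <- matrix(exp(rnorm(config$n_batches * n_amp, 0, config$batch_sd)),
                         nrow = config$n_batches)
    world <- structure(list(panel = panel, base_p = base_p,
                            batch_mult = batch_mult), class = "sim_world")
  } else {
    stopifnot(inherits(world, "sim_world"))
    panel <- world$panel
    base_p <- world$base_p
    batch_mult <- world$batch_mult
    if (config$n_batches > nrow(batch_mult)) {
      abort("config asks for more batches than the supplied world defines")
    }
  }
  n_amp <- nrow(panel)
  n <- config$n_controls + config$n_cancers
  is_cancer <- c(rep(FALSE, config$n_controls), rep(TRUE, config$n_cancers))
  ids <- sprintf("S%03d", seq_len(n))
  batch <- rep_len(seq_len(config$n_batches), n)
  tf <- ifelse(is_cancer,
               runif(n, config$tumor_fraction_range[1], config$tumor_fraction_range[2]),
               0)
  arms <- unique(panel$arm)
  n_alt <- ifelse(is_cancer,
                  sample(seq(config$n_altered_range[1], config$n_altered_range[2]),
                         n, replace = TRUE), 0L)
  altered <- lapply(seq_len(n), function(i) {
    if (n_alt[i] == 0) character(0) else sample(arms, n_alt[i])
  })
  gain <- lapply(seq_len(n), function(i) {
    if (n_alt[i] == 0) logical(0) else sample(c(TRUE, FALSE), n_alt[i], replace = TRUE)
  })
  len_c <- panel$insert_length - min(panel$insert_length)
  depth <- round(runif(n, 0.8, 1.2) * config$depth_mean)
  prop <- matrix(0, n, n_amp, dimnames = list(ids, panel$amplicon_id))
  arm_idx <- split(seq_len(n_amp), panel$arm)
  for (i in seq_len(n)) {
    # per-subject biological profile, shared by duplicate aliquots of the
    # same sample (between-subject variability beyond tumor burden). The
    # jitter redistributes amplifiability within arms only: in a euploid
    # subject arm dosage is fixed by karyotype, so arm totals must not
    # drift with locus-level biology.
    p0 <- base_p * batch_mult[batch[i], ]
    jit <- exp(rnorm(n_amp, 0, config$subject_sd))
    p <- p0 * jit
    for (ix in arm_idx) p[ix] <- p[ix] * (sum(p0[ix]) / sum(p[ix]))
    if (is_cancer[i]) {
      # log-linear fragmentation tilt: slope beta * t per bp of insert length
      p <- p * exp(-config$frag_beta * tf[i] * len_c)
      for (j in seq_along(altered[[i]])) {
        f <- if (gain[[i]][j]) 1 + tf[i] / 2 else 1 - tf[i] / 2
        p[panel$arm == altered[[i]][j]] <- p[panel$arm == altered[[i]][j]] * f
      }
    }
    prop[i, ] <- p / sum(p)
  }
  truth <- tibble::tibble(
    sample_id = ids,
    group = ifelse(is_cancer, "cancer", "non_cancer"),
    batch = paste0("batch", batch),
    tumor_fraction = tf,
    n_altered = n_alt,
    altered_arms = purrr::map_chr(altered, paste, collapse = ","),
    gains = purrr::map_chr(gain, function(g) paste(as.integer(g), collapse = ",")),
    depth = depth
  )
  draw <- function() {
    m <- matrix(rnbinom(n * n_amp, mu = as.vector(prop * depth),
                        size = 1 / config$dispersion),
                n, n_amp, dimnames = dimnames(prop))
    count_matrix(m, batch = truth$batch, panel = panel)
  }
  counts <- draw()
  out <- list(world = world, panel = panel, counts = counts,
              cohort = as_cohort_table(truth[c("sample_id", "group")]),
              truth = truth)
  if (!is.null(replicate_seed)) {
    set.seed(replicate_seed)
    out$counts_rep <- draw()
  }
  out
}

#' Generate a synthetic 17-analyte protein table
#'
#' Analyte baselines are log-normal; in case samples a configurable subset
#' of analytes is multiplied by `exp(protein_effect)`.
#'
#' @param config A [sim_config()].
#' @param labels Case/control labels, one per sample.
#' @param seed Integer seed.
#' @param world A `protein_world` from a previous call (attribute `world`
#'   of its result): fixed analyte baselines and affected-analyte set, so
#'   further samples (e.g. a calibration or held-out control panel) come
#'   from the same assay universe. `NULL` draws a fresh one.
#' @return A `protein_table`; attribute `world` carries the baselines and
#'   the names of the case-elevated analytes.
#' @export
gen_proteins <- function(config = sim_config(), labels, seed = 1L, world = NULL) {
  set.seed(seed)
  is_case <- as_case_label(labels)
  n <- length(is_case)
  if (is.null(world)) {
    world <- structure(list(
      meanlog = runif(17, 1, 3),
      affected = sample(PROTEIN17_ANALYTES, config$protein_n_affected)
    ), class = "protein_world")
  } else {
    stopifnot(inherits(world, "protein_world"))
  }
  meanlog <- world$meanlog
  affected <- world$affected
  x <- sapply(seq_len(17), function(j) {
    v <- exp(rnorm(n, meanlog[j], config$protein_sdlog))
    if (PROTEIN17_ANALYTES[j] %in% affected) {
      v[is_case] <- v[is_case] * exp(config$protein_effect)
    }
    v
  })
  colnames(x) <- PROTEIN17_ANALYTES
  out <- as_protein_table(tibble::tibble(
    sample_id = sprintf("P%03d", seq_len(n)),
    tibble::as_tibble(x)
  ))
  attr(out, "world") <- world
  out
}

#' Generate a synthetic multi-well mutation read table
#'
#' For each target mutation with true plasma MAF `true_mafs[i]`, mutant
#' templates per well are binomial at the per-well genome-equivalent
#' count; reads are then drawn at the template fraction perturbed by the
#' per-read error rate. Non-target variants (and the matched control run)
#' carry error-driven reads only.
#'
#' @param config A [sim_config()].
#' @param true_mafs Named numeric vector of true mutant allele fractions
#'   in \[0, 1), one per target mutation.
#' @param sample_id Sample identifier for the generated rows.
#' @param n_nontarget Number of non-target noise variants per sample.
#' @param seed Integer seed.
#' @return List with `wells` (targets + non-target variants) and
#'   `control_wells` (matched no-cancer control run over the same
#'   amplicons), both `well_table`s.
#' @export
gen_wells <- function(config = sim_config(), true_mafs, sample_id = "S001",
                      n_nontarget = 60, seed = 1L) {
  stopifnot(all(true_mafs >= 0), all(true_mafs < 1))
  set.seed(seed)
  if (is.null(names(true_mafs))) {
    names(true_mafs) <- sprintf("MUT%02d", seq_along(true_mafs))
  }
  W <- config$wells
  ge <- config$genome_equivalents
  err <- config$error_rate
  one_variant <- function(id, maf, target) {
    templates <- rbinom(W, ge, maf)
    frac <- templates / ge
    p_read <- frac * (1 - err) + (1 - frac) * err
    total <- rnbinom(W, mu = config$well_depth, size = 10)
    tibble::tibble(
      sample_id = sample_id, mutation_id = id, well_index = seq_len(W),
      mutant_reads = rbinom(W, total, p_read), total_reads = total,
      is_target = target
    )
  }
  targets <- purrr::imap_dfr(as.list(true_mafs), function(maf, id)
    one_variant(id, maf, TRUE))
  nontargets <- purrr::map_dfr(seq_len(n_nontarget), function(i)
    one_variant(sprintf("NT%02d", i), 0, FALSE))
  ctrl <- purrr::imap_dfr(as.list(true_mafs), function(maf, id)
    one_variant(id, 0, TRUE))
  ctrl$sample_id <- "CONTROL"
  ctrl$is_target <- FALSE
  list(
    wells = as_well_table(dplyr::bind_rows(targets, nontargets)),
    control_wells = as_well_table(ctrl)
  )
}
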