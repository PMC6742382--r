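#' Synthetic multi-platform callset generator
#'
#' Generates multi-sample mutation callsets with the statistical structure the
#' estimators assume, so that every rate estimator can be validated by
#' parameter recovery without external data: a truth catalogue of somatic
#' calls with clonal/subclonal allele-frequency mixture, CpG flags and
#' gene-group-dependent sequencing depth; "database" platform observations
#' with a logistic detection model (false-negative mechanism), injected false
#' positives at low allele frequency, and beta-binomial re-measurement noise;
#' deep-sequencing technical replicates whose detection falls off below the
#' high-frequency cutoff; and near-universal germline contaminant loci.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults emulate the scale of a 35-cell-line, 151-gene targeted-sequencing
#' study: about 620 high-frequency truth calls with an equally large
#' low-frequency tail, platform detection averaging 0.55 over high-frequency
#' calls (45% false-negative rate), a false-positive injection rate giving an
#' adjusted false-positive rate near 6%, and three germline contaminant loci
#' recurring in more than 80% of samples.
#'
#' @param n_samples number of samples (cell lines).
#' @param n_genes number of genes on the panel.
#' @param mut_rate expected truth mutations per gene per sample.
#' @param clonal_weight mixture weight of the clonal component of the truth
#'   allele-frequency distribution (`Beta(8, 8)`, centered 0.5); the
#'   remainder is subclonal (`Beta(2, 64)`, centered ~0.03).
#' @param cpg_fraction fraction of truth calls inside CpG islands.
#' @param high_fn_gene_fraction fraction of genes assigned to the
#'   low-coverage ("high false-negative") gene group.
#' @param depth_mean_low,depth_mean_high platform negative-binomial depth
#'   means for low-FN-group and high-FN-group genes.
#' @param depth_size negative-binomial size (dispersion) for platform depth.
#' @param base_detection marginal platform detection probability over
#'   high-frequency truth calls (the injected 1 - P-FN).
#' @param cpg_or odds multiplier on detection for CpG calls (< 1 means CpG
#'   calls are harder to detect; 1 disables the CpG effect).
#' @param depth_coef logistic coefficient of detection on standardized
#'   log-depth.
#' @param low_maf_penalty log-odds shift applied to platform detection of
#'   sub-cutoff (mAF < 10%) truth calls; strongly negative by default, since
#'   moderate-depth platforms rarely call subclonal variants (this is what
#'   keeps database callsets dominated by high-frequency calls and exercises
#'   the low-frequency rescue pathway of the adjusted false-positive rate).
#' @param fp_rate expected false-positive calls per sample per platform.
#' @param overdispersion beta-binomial intraclass correlation for re-measured
#'   allele frequencies (0 = pure binomial).
#' @param n_contaminants number of germline contaminant loci planted.
#' @param contaminant_fraction_range carrier-fraction range for contaminants
#'   (drawn uniformly; above the 0.8 recurrence threshold by default).
#' @param rep_depth_mean,rep_depth_size replicate (deep reference) depth
#'   negative-binomial parameters.
#' @param rep_hmaf_detect replicate detection probability for calls at or
#'   above 10% allele frequency.
#' @param rep_detect_intercept,rep_detect_slope logistic-in-log10(mAF)
#'   replicate detection curve below 10% (`plogis(intercept +
#'   slope * log10(maf))`), tuned so per-bin replicate consistency climbs
#'   from ~20% below 1% mAF to ~98% at 10%.
#' @param seed integer seed; the seed fully determines every generated object.
#' @return a `fnscope_sim_config` list.
#' @export
simulation_config <- function(n_samples = 35L,
                              n_genes = 151L,
                              mut_rate = 0.235,
                              clonal_weight = 0.5,
                              cpg_fraction = 0.15,
                              high_fn_gene_fraction = 0.5,
                              depth_mean_low = 150,
                              depth_mean_high = 60,
                              depth_size = 4,
                              base_detection = 0.55,
                              cpg_or = 0.35,
                              depth_coef = 0.8,
                              low_maf_penalty = -4,
                              fp_rate = 0.6,
                              overdispersion = 0.01,
                              n_contaminants = 3L,
                              contaminant_fraction_range = c(0.82, 0.97),
                              rep_depth_mean = 1000,
                              rep_depth_size = 8,
                              rep_hmaf_detect = 0.99,
                              rep_detect_intercept = 8.0,
                              rep_detect_slope = 3.8,
                              seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    mut_rate = mut_rate, clonal_weight = clonal_weight,
    cpg_fraction = cpg_fraction,
    high_fn_gene_fraction = high_fn_gene_fraction,
    depth_mean_low = depth_mean_low, depth_mean_high = depth_mean_high,
    depth_size = depth_size,
    base_detection = base_detection, cpg_or = cpg_or,
    depth_coef = depth_coef, low_maf_penalty = low_maf_penalty,
    fp_rate = fp_rate,
    overdispersion = overdispersion,
    n_contaminants = as.integer(n_contaminants),
    contaminant_fraction_range = contaminant_fraction_range,
    rep_depth_mean = rep_depth_mean, rep_depth_size = rep_depth_size,
    rep_hmaf_detect = rep_hmaf_detect,
    rep_detect_intercept = rep_detect_intercept,
    rep_detect_slope = rep_detect_slope,
    seed = as.integer(seed)
  )
  check_fraction <- function(name, lo = 0, hi = 1) {
    v <- cfg[[name]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < lo) || any(v > hi)) {
      abort(sprintf("invalid simulation config field '%s'", name),
            class = "fnscope_config_error")
    }
  }
  for (f in c("clonal_weight", "cpg_fraction", "high_fn_gene_fraction",
              "base_detection", "overdispersion", "rep_hmaf_detect",
              "contaminant_fraction_range")) check_fraction(f)
  for (f in c("n_samples", "n_genes")) {
    if (cfg[[f]] < 1) abort(sprintf("invalid simulation config field '%s'", f),
                            class = "fnscope_config_error")
  }
  if (cfg$mut_rate < 0 || cfg$fp_rate < 0 || cfg$cpg_or < 0 ||
      cfg$n_contaminants < 0) {
    abort("rates and odds multipliers must be non-negative",
          class = "fnscope_config_error")
  }
  structure(cfg, class = "fnscope_sim_config")
}

#' Named scenario presets
#'
#' \describe{
#'   \item{`paper_like`}{the defaults: ~45% platform false negatives, ~6%
#'     adjusted false positives, CpG detection odds multiplier 0.35, three
#'     germline contaminants.}
#'   \item{`null_no_cpg_effect`}{CpG odds multiplier exactly 1 (no CpG
#'     effect), for type-I-error calibration of the CpG association test.}
#'   \item{`null_no_group_effect`}{equal platform depth means across gene
#'     groups (no gene-group effect), for calibration of the group test.}
#'   \item{`high_fp`}{false-positive injection raised to 6 calls/sample.}
#' }
#'
#' @param name preset name.
#' @param ... overrides passed to [simulation_config()].
#' @return a `fnscope_sim_config`.
#' @export
scenario_preset <- function(name = c("paper_like", "null_no_cpg_effect",
                                     "null_no_group_effect", "high_fp"),
                            ...) {
  if (!is.character(name) || !(name[1] %in%
        c("paper_like", "null_no_cpg_effect", "null_no_group_effect",
          "high_fp"))) {
    abort(paste0("unknown preset '", name[1], "'; available: paper_like, ",
                 "null_no_cpg_effect, null_no_group_effect, high_fp"),
          class = "fnscope_config_error")
  }
  name <- name[1]
  extra <- switch(name,
    paper_like = list(),
    null_no_cpg_effect = list(cpg_or = 1),
    null_no_group_effect = list(depth_mean_low = 100, depth_mean_high = 100),
    high_fp = list(fp_rate = 6)
  )
  do.call(simulation_config, modifyList(extra, list(...)))
}

sim_seed <- function(cfg, offset) (cfg$seed + offset) %% 2147483647L

# Gene table: symbol, chromosome, window base position, gene group.
sim_genes <- function(cfg) {
  g <- sprintf("GENE%03d", seq_len(cfg$n_genes))
  n_high <- round(cfg$n_genes * cfg$high_fn_gene_fraction)
  tibble::tibble(
    gene = g,
    chrom = as.character(rep_len(1:22, cfg$n_genes)),
    base_pos = 1e6 + (seq_len(cfg$n_genes) - 1) * 1e5,
    gene_group = rep(c("high", "low"),
                     c(n_high, cfg$n_genes - n_high))[order(runif(cfg$n_genes))]
  )
}

rbetabinom <- function(n, size, prob, rho) {
  if (rho <= 0) return(rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  p <- rbeta(n, pmax(a, 1e-8), pmax(b, 1e-8))
  rbinom(n, size, p)
}

#' Simulate the truth catalogue
#'
#' Draws, per sample and gene, a Poisson number of true somatic mutations
#' with the configured rate; assigns each call its gene group, CpG flag,
#' true allele frequency (clonal/subclonal Beta mixture) and deep-reference
#' depth; and plants `n_contaminants` germline frameshift loci carried by
#' more than the recurrence-threshold fraction of samples (with missing
#' population allele frequency, as unreported polymorphisms).
#'
#' @param cfg a [simulation_config()].
#' @return a `fnscope_truth_catalogue`: tibble of canonical call columns plus
#'   `true_maf`, `gene_group`, `is_contaminant`.
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "fnscope_sim_config"))
  set.seed(sim_seed(cfg, 0L))
  genes <- sim_genes(cfg)
  samples <- sprintf("CELL%03d", seq_len(cfg$n_samples))
  # somatic calls
  lam <- cfg$mut_rate
  counts <- rpois(cfg$n_samples * cfg$n_genes, lam)
  idx <- rep(seq_along(counts), counts)
  n <- length(idx)
  gi <- ((idx - 1) %% cfg$n_genes) + 1
  si <- ((idx - 1) %/% cfg$n_genes) + 1
  clonal <- runif(n) < cfg$clonal_weight
  true_maf <- ifelse(clonal, rbeta(n, 8, 8), rbeta(n, 2, 64))
  true_maf <- pmin(pmax(true_maf, 0.001), 0.999)
  depth <- pmax(rnbinom(n, mu = cfg$rep_depth_mean, size = cfg$rep_depth_size),
                30L)
  alt <- pmax(round(true_maf * depth), 1L)
  pos <- genes$base_pos[gi] + sample.int(2e4, n, replace = TRUE)
  df <- tibble::tibble(
    sample_id = samples[si],
    gene = genes$gene[gi],
    chrom = genes$chrom[gi],
    pos = as.integer(pos),
    ref_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    variant_class = sample(c("Missense", "Nonsense", "Splice_Site",
                             "Frame_Shift_Del", "In_Frame_Del"),
                           n, replace = TRUE,
                           prob = c(0.7, 0.1, 0.05, 0.1, 0.05)),
    protein_change = sprintf("p.X%dY", as.integer(pos) %% 1000 + 1),
    alt_count = as.integer(alt),
    ref_count = as.integer(depth - alt),
    population_af = NA_real_,
    in_cpg_island = runif(n) < cfg$cpg_fraction,
    true_maf = true_maf,
    gene_group = genes$gene_group[gi],
    is_contaminant = FALSE
  )
  # avoid duplicate loci within a sample
  df <- df[!duplicated(paste(df$sample_id, df$chrom, df$pos)), , drop = FALSE]
  # germline contaminants: frameshift loci carried by most samples
  if (cfg$n_contaminants > 0) {
    cont <- lapply(seq_len(cfg$n_contaminants), function(i) {
      g <- (i - 1) %% cfg$n_genes + 1
      frac <- runif(1, cfg$contaminant_fraction_range[1],
                    cfg$contaminant_fraction_range[2])
      carriers <- sample(samples, max(1, round(frac * cfg$n_samples)))
      m <- length(carriers)
      maf <- pmin(pmax(rbeta(m, 40, 40), 0.05), 0.95)
      depth <- pmax(rnbinom(m, mu = cfg$rep_depth_mean,
                            size = cfg$rep_depth_size), 30L)
      alt <- pmax(round(maf * depth), 1L)
      tibble::tibble(
        sample_id = carriers,
        gene = genes$gene[g],
        chrom = genes$chrom[g],
        pos = as.integer(genes$base_pos[g] + 90000 + i),
        ref_allele = "A",
        alt_allele = "-",
        variant_class = "Frame_Shift_Del",
        protein_change = sprintf("p.G%dfs", 100 + i),
        alt_count = as.integer(alt),
        ref_count = as.integer(depth - alt),
        population_af = NA_real_,
        in_cpg_island = FALSE,
        true_maf = maf,
        gene_group = genes$gene_group[g],
        is_contaminant = TRUE
      )
    })
    df <- dplyr::bind_rows(df, dplyr::bind_rows(cont))
  }
  structure(df, class = c("fnscope_truth_catalogue", class(df)))
}

#' Convert a truth catalogue to a callset
#'
#' @param catalogue a [simulate_truth()] result.
#' @param source_label label for the callset (default `"truth"`).
#' @param key_scheme key scheme.
#' @param drop_contaminants drop planted germline contaminant loci first
#'   (default `FALSE`).
#' @return a `fnscope_callset`.
#' @export
catalogue_as_callset <- function(catalogue, source_label = "truth",
                                 key_scheme = "genomic",
                                 drop_contaminants = FALSE) {
  df <- tibble::as_tibble(catalogue)
  if (drop_contaminants) df <- df[!df$is_contaminant, , drop = FALSE]
  callset(df, source_label = source_label, key_scheme = key_scheme)
}

#' Simulate one platform's observation of the truth
#'
#' Each truth call is detected independently with probability
#' `plogis(intercept + log(cpg_or) * in_cpg_island + depth_coef * z)`, where
#' `z` is the standardized log platform depth (drawn per call from the
#' gene-group negative binomial) and the intercept is calibrated so the
#' *marginal* detection probability over high-frequency (mAF >= 0.10) truth
#' calls equals `base_detection` exactly — making the injected false-negative
#' rate well-defined for parameter recovery. Detected calls re-measure their
#' allele frequency with beta-binomial noise at the platform depth.
#' False-positive calls are injected at novel loci (Poisson with mean
#' `fp_rate * n_samples`) with low allele frequencies (Beta(2, 38)).
#'
#' @param catalogue a [simulate_truth()] result.
#' @param cfg the [simulation_config()] used to generate it.
#' @param platform_label label for the platform, e.g. `"DB1"`.
#' @param seed optional integer seed; defaults to a label-derived offset of
#'   `cfg$seed` so different platforms of one study are independent.
#' @return a `fnscope_callset` with attribute `provenance`: tibble of
#'   (`key`, `in_truth`, `detected`, `p_detect`, `is_fp`) for every truth
#'   call and injected false positive.
#' @export
simulate_platform <- function(catalogue, cfg, platform_label, seed = NULL) {
  stopifnot(inherits(catalogue, "fnscope_truth_catalogue"),
            inherits(cfg, "fnscope_sim_config"))
  if (is.null(seed)) {
    seed <- sim_seed(cfg, 1000L + sum(utf8ToInt(platform_label)))
  }
  set.seed(seed)
  df <- tibble::as_tibble(catalogue)
  n <- nrow(df)
  mu <- ifelse(df$gene_group == "high", cfg$depth_mean_high,
               cfg$depth_mean_low)
  pdepth <- pmax(rnbinom(n, mu = mu, size = cfg$depth_size), 5L)
  logd <- log(pdepth)
  z <- if (n > 1 && stats::sd(logd) > 0) (logd - mean(logd)) / stats::sd(logd)
       else rep(0, n)
  offset <- log(cfg$cpg_or) * as.numeric(df$in_cpg_island) +
            cfg$depth_coef * z
  maf <- df$alt_count / (df$alt_count + df$ref_count)
  hm <- maf >= 0.10
  offset <- offset + cfg$low_maf_penalty * as.numeric(!hm)
  p_detect <- calibrated_detection(offset, hm, cfg$base_detection)
  detected <- runif(n) < p_detect
  obs_alt <- rbetabinom(n, pdepth, maf, cfg$overdispersion)
  obs_alt <- pmax(obs_alt, 1L)  # a detected call has at least one read
  obs <- df[detected, intersect(CALL_COLUMNS, names(df)), drop = FALSE]
  obs$alt_count <- as.integer(obs_alt[detected])
  obs$ref_count <- as.integer(pdepth[detected] - obs_alt[detected])
  # false positives at novel loci (disjoint position window per gene)
  genes <- sim_genes_lookup(df)
  n_fp <- rpois(1, cfg$fp_rate * cfg$n_samples)
  if (n_fp > 0) {
    gi <- sample.int(nrow(genes), n_fp, replace = TRUE)
    fdepth <- pmax(rnbinom(n_fp, mu = cfg$depth_mean_low,
                           size = cfg$depth_size), 5L)
    fmaf <- rbeta(n_fp, 2, 38)
    falt <- pmax(rbinom(n_fp, fdepth, fmaf), 1L)
    fp <- tibble::tibble(
      sample_id = sample(unique(df$sample_id), n_fp, replace = TRUE),
      gene = genes$gene[gi],
      chrom = genes$chrom[gi],
      pos = as.integer(genes$base_pos[gi] + 3e4 +
                       sample.int(2e4, n_fp, replace = TRUE)),
      ref_allele = sample(c("A", "C", "G", "T"), n_fp, replace = TRUE),
      alt_allele = sample(c("A", "C", "G", "T"), n_fp, replace = TRUE),
      variant_class = "Missense",
      protein_change = sprintf("p.F%dP", seq_len(n_fp)),
      alt_count = as.integer(falt),
      ref_count = as.integer(fdepth - falt),
      population_af = NA_real_,
      in_cpg_island = runif(n_fp) < cfg$cpg_fraction
    )
    fp <- fp[!duplicated(paste(fp$sample_id, fp$chrom, fp$pos,
                               fp$ref_allele, fp$alt_allele)), , drop = FALSE]
    n_fp <- nrow(fp)
    obs <- dplyr::bind_rows(obs, fp)
  }
  out <- callset(obs, source_label = platform_label, key_scheme = "genomic")
  truth_keys <- paste(df$sample_id, df$chrom, df$pos,
                      df$ref_allele, df$alt_allele, sep = "|")
  prov <- tibble::tibble(
    key = c(truth_keys,
            if (n_fp > 0) make_key(callset(fp, "fp")) else character(0)),
    in_truth = c(rep(TRUE, n), rep(FALSE, n_fp)),
    detected = c(detected, rep(TRUE, n_fp)),
    p_detect = c(p_detect, rep(NA_real_, n_fp)),
    is_fp = c(rep(FALSE, n), rep(TRUE, n_fp))
  )
  attr(out, "provenance") <- prov
  out
}

# Solve for the logistic intercept making mean detection over high-frequency
# calls equal the requested marginal rate.
calibrated_detection <- function(offset, hm, base_detection) {
  if (base_detection >= 1) return(rep(1, length(offset)))
  if (base_detection <= 0) return(rep(0, length(offset)))
  if (!any(hm)) return(plogis(qlogis(base_detection) + offset))
  f <- function(c0) mean(plogis(c0 + offset[hm])) - base_detection
  c0 <- uniroot(f, lower = -30, upper = 30, tol = 1e-10)$root
  plogis(c0 + offset)
}

sim_genes_lookup <- function(df) {
  g <- df[!duplicated(df$gene), c("gene", "chrom"), drop = FALSE]
  # recover the per-gene base position used by the generator
  g$base_pos <- 1e6 + (as.integer(sub("GENE", "", g$gene)) - 1) * 1e5
  g
}

#' Simulate two deep-sequencing technical replicates
#'
#' Both replicates observe the truth catalogue with detection probability
#' `rep_hmaf_detect` for calls at or above 10% allele frequency and
#' `plogis(rep_detect_intercept + rep_detect_slope * log10(maf))` below it,
#' re-measuring allele frequencies with beta-binomial noise at deep
#' (reference-scale) depth, with the platform false-positive mechanism.
#'
#' @param catalogue a [simulate_truth()] result.
#' @param cfg the [simulation_config()].
#' @param labels labels for the two replicate callsets.
#' @return list of two `fnscope_callset`s.
#' @export
simulate_replicates <- function(catalogue, cfg,
                                labels = c("TarSeq1", "TarSeq2")) {
  stopifnot(inherits(catalogue, "fnscope_truth_catalogue"),
            inherits(cfg, "fnscope_sim_config"))
  df <- tibble::as_tibble(catalogue)
  n <- nrow(df)
  maf <- df$alt_count / (df$alt_count + df$ref_count)
  p_detect <- ifelse(maf >= 0.10, cfg$rep_hmaf_detect,
                     pmin(plogis(cfg$rep_detect_intercept +
                                 cfg$rep_detect_slope * log10(pmax(maf, 1e-6))),
                          cfg$rep_hmaf_detect))
  one_rep <- function(label, offset) {
    set.seed(sim_seed(cfg, 2000L + offset))
    detected <- runif(n) < p_detect
    depth <- pmax(rnbinom(n, mu = cfg$rep_depth_mean,
                          size = cfg$rep_depth_size), 30L)
    alt <- pmax(rbetabinom(n, depth, maf, cfg$overdispersion), 1L)
    obs <- df[detected, intersect(CALL_COLUMNS, names(df)), drop = FALSE]
    obs$alt_count <- as.integer(alt[detected])
    obs$ref_count <- as.integer(depth[detected] - alt[detected])
    n_fp <- rpois(1, cfg$fp_rate * cfg$n_samples)
    if (n_fp > 0) {
      genes <- sim_genes_lookup(df)
      gi <- sample.int(nrow(genes), n_fp, replace = TRUE)
      fdepth <- pmax(rnbinom(n_fp, mu = cfg$rep_depth_mean,
                             size = cfg$rep_depth_size), 30L)
      fmaf <- rbeta(n_fp, 2, 38)
      falt <- pmax(rbinom(n_fp, fdepth, fmaf), 1L)
      fp <- tibble::tibble(
        sample_id = sample(unique(df$sample_id), n_fp, replace = TRUE),
        gene = genes$gene[gi],
        chrom = genes$chrom[gi],
        pos = as.integer(genes$base_pos[gi] + 55000L + offset * 15000L +
                         sample.int(15000, n_fp, replace = TRUE)),
        ref_allele = sample(c("A", "C", "G", "T"), n_fp, replace = TRUE),
        alt_allele = sample(c("A", "C", "G", "T"), n_fp, replace = TRUE),
        variant_class = "Missense",
        protein_change = sprintf("p.R%dQ", seq_len(n_fp)),
        alt_count = as.integer(falt),
        ref_count = as.integer(fdepth - falt),
        population_af = NA_real_,
        in_cpg_island = FALSE
      )
      obs <- dplyr::bind_rows(obs, fp)
    }
    callset(obs, source_label = label, key_scheme = "genomic")
  }
  list(one_rep(labels[1], 0L), one_rep(labels[2], 1L))
}

#' Simulate a full study
#'
#' Convenience wrapper generating the truth catalogue, two database-style
#' platform observations and two deep-sequencing replicates under one
#' configuration.
#'
#' @param cfg a [simulation_config()] or [scenario_preset()] result.
#' @param platform_labels labels for the two database platforms.
#' @return a `fnscope_simulated_study`: list with `truth_catalogue`,
#'   `platforms` (list of callsets with provenance attributes) and
#'   `replicates` (list of two callsets).
#' @export
simulate_study <- function(cfg = scenario_preset("paper_like"),
                           platform_labels = c("DB1", "DB2")) {
  truth <- simulate_truth(cfg)
  platforms <- lapply(platform_labels, function(lab)
    simulate_platform(truth, cfg, lab))
  names(platforms) <- platform_labels
  reps <- simulate_replicates(truth, cfg)
  structure(list(truth_catalogue = truth, platforms = platforms,
                 replicates = reps, config = cfg),
            class = "fnscope_simulated_study")
}
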