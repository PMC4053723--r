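#' Configuration for the synthetic XCI cohort generator
#'
#' Builds the parameter list consumed by [simulate_cohort()] and
#' [simulate_chip()]. Defaults describe a cohort of three sample sets (two
#' lymphoblastoid-cell-line populations and one fibroblast set) of 20 females
#' each, 200 X-linked genes laid out in positional runs of shared XCI status
#' (a PAR1 block, escape blocks, variable-escape blocks of all three subtypes,
#' subject blocks, and one planted imprinted gene), an autosomal probe
#' background with a ~10% cis-imbalanced minority, intensity-dependent AI
#' noise following a one-phase decay, and a small rate of genomic-DNA ratio
#' artifacts.
#'
#' @param n_females_per_set Females per sample set.
#' @param sample_sets Named character vector: sample-set labels, names give
#'   the cell type (`"LCL"` or `"fibroblast"`).
#' @param n_autosomal_probes Autosomal background probes.
#' @param probes_per_gene Integer range (length 2) of probes per X gene.
#' @param heterozygosity Per-probe, per-female probability of being
#'   heterozygous (informative).
#' @param skew_mix Data frame with columns `component`, `weight`, `lo`, `hi`:
#'   mixture of uniform components the per-female true skew is drawn from.
#' @param noise_base_sd,noise_amplitude,noise_tau AI noise model: the
#'   standard deviation of allele-fraction noise at total intensity `I` is
#'   `noise_base_sd + noise_amplitude * exp(-I / noise_tau)`.
#' @param intensity_meanlog,intensity_sdlog Log-normal total-intensity model.
#' @param gdna_artifact_rate Fraction of probes with a biased genomic-DNA
#'   ratio (centred at `gdna_artifact_ratio`) in one sample set.
#' @param gdna_artifact_ratio Genomic-DNA allele-1 ratio of artifact probes.
#' @param autosomal_imbalance_rate Fraction of autosomal probes with a cis
#'   allelic imbalance.
#' @param autosomal_ai_offset,autosomal_ai_scale The cis AI magnitude of an
#'   imbalanced autosomal probe is `offset + Exp(mean = scale)`, capped at
#'   0.45.
#' @param chip_class_means Named numeric: mean histone ChIP |AI| per
#'   expression class, decreasing from silenced to PAR1-like genes.
#' @param chip_sd Spread of per-probe ChIP AI around its class mean.
#' @param chip_marks Histone marks to simulate.
#' @param n_chip_samples Skewed females assayed per mark.
#' @param chip_body_factor Gene-body probes per promoter probe (~40, matching
#'   the relative informativity of the two regions).
#' @param seed Integer root seed; all randomness flows from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_females_per_set = 20,
                          sample_sets = c(LCL = "LCL1", LCL = "LCL2",
                                          fibroblast = "FIB"),
                          n_autosomal_probes = 2000,
                          probes_per_gene = c(2L, 8L),
                          heterozygosity = 0.35,
                          skew_mix = data.frame(
                            component = c("high", "moderate", "random"),
                            weight    = c(0.35, 0.40, 0.25),
                            lo        = c(0.85, 0.68, 0.50),
                            hi        = c(0.98, 0.85, 0.52)),
                          noise_base_sd = 0.02,
                          noise_amplitude = 0.15,
                          noise_tau = 2000,
                          intensity_meanlog = log(8000),
                          intensity_sdlog = 0.8,
                          gdna_artifact_rate = 0.02,
                          gdna_artifact_ratio = 0.85,
                          autosomal_imbalance_rate = 0.10,
                          autosomal_ai_offset = 0.05,
                          autosomal_ai_scale = 0.08,
                          chip_class_means = c(escape_in_PAR1_range = 0.12,
                                               escape_outside_PAR1_range = 0.22,
                                               subject_ge5 = 0.32,
                                               subject_lt5 = 0.40),
                          chip_sd = 0.08,
                          chip_marks = c("H3K4me1", "H3K4me3", "H3K27me3"),
                          n_chip_samples = 5,
                          chip_body_factor = 40,
                          seed = 1L) {
  stopifnot(n_females_per_set > 0, length(sample_sets) >= 1,
            length(probes_per_gene) == 2, probes_per_gene[1] >= 1,
            heterozygosity > 0, heterozygosity < 1,
            all(skew_mix$lo >= 0.5), all(skew_mix$hi <= 1),
            noise_base_sd >= 0, noise_tau > 0,
            gdna_artifact_rate >= 0, gdna_artifact_rate <= 1,
            autosomal_imbalance_rate >= 0, autosomal_imbalance_rate <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

# gene archetype layout: runs along the chromosome so statuses cluster
# positionally. Archetypes: par1, escape_tr (escape training), escape,
# var_bimodal / var_borderline / var_het, subject_tr (subject training),
# subject, imprinted.
gene_layout <- function() {
  runs <- list(
    c("par1", 8), c("escape_tr", 12), c("var_het", 4), c("subject_tr", 30),
    c("var_bimodal", 4), c("subject", 10), c("escape_tr", 10),
    c("escape", 6), c("var_borderline", 4), c("subject_tr", 40),
    c("imprinted", 1), c("subject", 11), c("var_het", 4), c("escape", 6),
    c("var_bimodal", 4), c("subject_tr", 30), c("var_borderline", 4),
    c("subject", 12))
  rep(vapply(runs, `[`, "", 1), times = as.integer(vapply(runs, `[`, "", 2)))
}

archetype_status <- function(archetype) {
  dplyr::case_match(archetype,
    c("par1", "escape_tr", "escape") ~ "escape",
    c("var_bimodal", "var_borderline", "var_het") ~ "variable_escape",
    c("subject_tr", "subject") ~ "subject",
    "imprinted" ~ "imprinted")
}

# Gene-level true xi for fixed-xi archetypes (NA for variable/imprinted,
# whose xi is drawn per female).
draw_gene_xi <- function(archetype) {
  n <- length(archetype)
  xi <- rep(NA_real_, n)
  idx <- archetype == "par1"
  xi[idx] <- stats::runif(sum(idx), 0.49, 0.75)
  idx <- archetype %in% c("escape_tr", "escape")
  xi[idx] <- stats::runif(sum(idx), 0.25, 0.75)
  idx <- archetype %in% c("subject_tr", "subject")
  k <- sum(idx)
  # most subject genes are fully silenced; a minority leak a few percent of
  # Xi expression (still below the 10% escape cutoff)
  u <- stats::runif(k)
  xi[idx] <- ifelse(u < 0.6, 0,
                    ifelse(u < 0.85, abs(stats::rnorm(k, 0, 0.015)),
                           stats::runif(k, 0.04, 0.07)))
  xi
}

# Per-female xi for variable-escape subtypes.
draw_variable_xi <- function(archetype, n) {
  switch(archetype,
    var_bimodal = ifelse(stats::runif(n) < 0.5, 0, 1),
    var_borderline = pmax(stats::rnorm(n, 0.10, 0.04), 0),
    var_het = ifelse(stats::runif(n) < 0.35,
                     stats::runif(n, 0, 0.08),
                     stats::runif(n, 0.12, 1)),
    stop("unknown variable archetype: ", archetype))
}

#' Simulate a synthetic allelic-imbalance cohort with ground truth
#'
#' Generates a probe table with the schema consumed by the pipeline (see
#' [read_probe_table()]) together with the ground truth needed to test every
#' downstream stage: per-female true skew, per-gene (and, for
#' variable-escape genes, per-gene-per-female) true Xi expression, gene
#' coordinates with PAR1 flags, the training-set gene lists, and the identity
#' of genomic-DNA artifact probes.
#'
#' For an informative (heterozygous) X probe the observed allele-1 fraction
#' is the forward model [expected_ai()] fraction at the female's true skew
#' and the gene's true xi, plus Gaussian noise whose standard deviation
#' decays with total intensity; homozygous probes sit at 0 or 1 plus the same
#' noise. Autosomal probes are balanced apart from a cis-imbalanced minority.
#' One planted gene is imprinted (mono-allelic in every female regardless of
#' skew) to exercise the group-R screen.
#'
#' @param config A [cohort_config()].
#' @return An object of class `xci_cohort`: a list with elements `probes`
#'   (tibble), `annotation` (tibble, BED-like gene table with `par1` flag),
#'   `truth` (list: `females`, `genes`, `gene_xi`, `autosomal`,
#'   `artifact_probes`), `training` (list: `subject`, `escape`), and
#'   `config`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_females_per_set = 2, seed = 7))
#' dplyr::glimpse(cohort$probes)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  archetype <- gene_layout()
  n_genes <- length(archetype)

  ## --- genes / annotation -------------------------------------------------
  width <- round(stats::runif(n_genes, 1e4, 1.5e5))
  start <- integer(n_genes)
  par1 <- archetype == "par1"
  start[par1] <- sort(round(stats::runif(sum(par1), 6e4, 2.4e6)))
  start[!par1] <- 3e6 + (seq_len(sum(!par1)) - 1L) * 760000L +
    round(stats::runif(sum(!par1), 0, 5e5))
  genes <- tibble::tibble(
    gene = sprintf("XG%03d", seq_len(n_genes)),
    chrom = "chrX",
    start = as.integer(start),
    end = as.integer(start + width),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    par1 = par1,
    archetype = archetype,
    true_status = archetype_status(archetype),
    true_xi = draw_gene_xi(archetype))

  annotation <- dplyr::select(genes, "chrom", "start", "end", "gene",
                              "strand", "par1")
  annotation$score <- 0L
  annotation <- annotation[, c("chrom", "start", "end", "gene", "score",
                               "strand", "par1")]

  training <- list(
    subject = genes$gene[genes$archetype == "subject_tr"],
    escape  = genes$gene[genes$archetype %in% c("par1", "escape_tr")])

  ## --- females ------------------------------------------------------------
  sets <- unname(cfg$sample_sets)
  cell_type <- stats::setNames(names(cfg$sample_sets), sets)
  n_f <- cfg$n_females_per_set
  females <- tidyr::expand_grid(sample_set = sets, idx = seq_len(n_f))
  comp <- sample(cfg$skew_mix$component, nrow(females), replace = TRUE,
                 prob = cfg$skew_mix$weight)
  mix <- cfg$skew_mix[match(comp, cfg$skew_mix$component), ]
  females <- dplyr::mutate(females,
    sample_id = sprintf("%s_F%02d", .data$sample_set, .data$idx),
    skew_component = comp,
    true_skew = stats::runif(dplyr::n(), mix$lo, mix$hi),
    idx = NULL)

  ## --- probes -------------------------------------------------------------
  n_per_gene <- sample(seq(cfg$probes_per_gene[1], cfg$probes_per_gene[2]),
                       n_genes, replace = TRUE)
  x_probes <- tibble::tibble(
    gene = rep(genes$gene, n_per_gene),
    chrom = "chrX",
    pos = as.integer(rep(genes$start, n_per_gene) +
      round(stats::runif(sum(n_per_gene))) +
      round(stats::runif(sum(n_per_gene)) * rep(width, n_per_gene))),
    probe_id = sprintf("pX%04d", seq_len(sum(n_per_gene))))

  n_auto <- cfg$n_autosomal_probes
  auto_probes <- tibble::tibble(
    gene = NA_character_,
    chrom = sample(paste0("chr", 1:22), n_auto, replace = TRUE),
    pos = as.integer(round(stats::runif(n_auto, 1e5, 1e8))),
    probe_id = sprintf("pA%04d", seq_len(n_auto)),
    imbalanced = stats::runif(n_auto) < cfg$autosomal_imbalance_rate,
    cis_ai = pmin(cfg$autosomal_ai_offset +
                    stats::rexp(n_auto, 1 / cfg$autosomal_ai_scale), 0.45))
  auto_probes$cis_ai[!auto_probes$imbalanced] <- 0

  probes_all <- dplyr::bind_rows(
    dplyr::select(x_probes, "probe_id", "gene", "chrom", "pos"),
    dplyr::select(auto_probes, "probe_id", "gene", "chrom", "pos"))

  # genomic-DNA artifact probes: biased ratio in one (random) sample set
  n_p <- nrow(probes_all)
  is_artifact <- stats::runif(n_p) < cfg$gdna_artifact_rate
  artifact_set <- ifelse(is_artifact, sample(sets, n_p, replace = TRUE),
                         NA_character_)

  ## --- measurements: one row per probe x female ---------------------------
  grid <- tidyr::expand_grid(
    probe_id = probes_all$probe_id,
    sample_id = females$sample_id)
  grid <- dplyr::left_join(grid, probes_all, by = "probe_id")
  grid <- dplyr::left_join(
    grid, dplyr::select(females, "sample_id", "sample_set", "true_skew"),
    by = "sample_id")

  m <- nrow(grid)
  grid$informative <- stats::runif(m) < cfg$heterozygosity
  grid$intensity <- stats::rlnorm(m, cfg$intensity_meanlog,
                                  cfg$intensity_sdlog)
  noise_sd <- cfg$noise_base_sd +
    cfg$noise_amplitude * exp(-grid$intensity / cfg$noise_tau)

  # true xi per (gene, female): fixed for most archetypes, per-female draws
  # for variable-escape genes
  grid <- dplyr::left_join(
    grid,
    dplyr::select(genes, "gene", "archetype", "true_xi"),
    by = "gene")
  gene_xi <- tidyr::expand_grid(
    gene = genes$gene[genes$true_status == "variable_escape"],
    sample_id = females$sample_id)
  gene_xi <- dplyr::left_join(
    gene_xi, dplyr::select(genes, "gene", "archetype"), by = "gene")
  gene_xi <- gene_xi |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(true_xi = draw_variable_xi(.data$archetype[1],
                                             dplyr::n())) |>
    dplyr::ungroup() |>
    dplyr::select("gene", "sample_id", "true_xi")
  grid <- dplyr::left_join(grid, gene_xi, by = c("gene", "sample_id"),
                           suffix = c("", "_vf"))
  grid$true_xi <- dplyr::coalesce(grid$true_xi_vf, grid$true_xi)

  # expected allele-1 fraction before noise
  is_x <- !is.na(grid$gene)
  f_true <- numeric(m)
  sk <- grid$true_skew
  xi <- grid$true_xi
  f_true[is_x] <- ((sk + xi * (1 - sk)) / (1 + xi))[is_x]
  # random phase: which parental allele is allele 1 varies per gene x female
  phase_key <- paste(grid$gene, grid$sample_id)
  flip <- stats::runif(length(unique(phase_key))) < 0.5
  names(flip) <- unique(phase_key)
  f_true[is_x] <- ifelse(flip[phase_key[is_x]], 1 - f_true[is_x],
                         f_true[is_x])
  # imprinted gene: mono-allelic in every female, parent of origin random
  imp <- is_x & grid$archetype == "imprinted"
  f_true[imp] <- as.numeric(flip[phase_key[imp]])
  # autosomal: balanced, or cis-imbalanced with random direction per female
  auto_ai <- auto_probes$cis_ai[match(grid$probe_id, auto_probes$probe_id)]
  f_true[!is_x] <- 0.5 +
    ifelse(flip[phase_key[!is_x]], -1, 1) * auto_ai[!is_x]
  # homozygous probes: one allele only
  hom <- !grid$informative
  f_true[hom] <- round(stats::runif(sum(hom)))

  grid$frac_cdna <- pmin(pmax(f_true + stats::rnorm(m, 0, noise_sd), 0), 1)

  # genomic DNA channel: ~0.5 in heterozygotes, biased at artifact probes
  art_set <- artifact_set[match(grid$probe_id, probes_all$probe_id)]
  gdna <- ifelse(grid$informative,
                 0.5 + stats::rnorm(m, 0, 0.02),
                 f_true + stats::rnorm(m, 0, 0.01))
  art_here <- grid$informative & !is.na(art_set) &
    grid$sample_set == art_set
  gdna[art_here] <- cfg$gdna_artifact_ratio +
    stats::rnorm(sum(art_here), 0, 0.02)
  grid$frac_gdna <- pmin(pmax(gdna, 0), 1)

  probes <- grid |>
    dplyr::transmute(
      probe_id = .data$probe_id,
      gene = .data$gene,
      chrom = .data$chrom,
      pos = .data$pos,
      sample_id = .data$sample_id,
      sex = "F",
      sample_set = .data$sample_set,
      informative = .data$informative,
      intensity = round(.data$intensity, 2),
      frac_cdna = .data$frac_cdna,
      frac_gdna = .data$frac_gdna,
      channel = "expression") |>
    dplyr::arrange(.data$probe_id, .data$sample_id)

  truth <- list(
    females = dplyr::select(females, "sample_id", "sample_set",
                            "skew_component", "true_skew"),
    genes = genes,
    gene_xi = gene_xi,
    autosomal = dplyr::select(auto_probes, "probe_id", "imbalanced",
                              "cis_ai"),
    artifact_probes = probes_all$probe_id[is_artifact])

  structure(
    list(probes = probes, annotation = annotation, truth = truth,
         training = training, cell_type = cell_type, config = cfg),
    class = "xci_cohort")
}

#' @export
print.xci_cohort <- function(x, ...) {
  cat("<xci_cohort>\n")
  cat("  ", nrow(x$truth$females), "females in",
      length(unique(x$truth$females$sample_set)), "sample sets\n")
  cat("  ", nrow(x$truth$genes), "X-linked genes,",
      sum(is.na(x$probes$gene[!duplicated(x$probes$probe_id)])),
      "autosomal probes\n")
  cat("  ", nrow(x$probes), "probe measurements\n")
  invisible(x)
}

#' Simulate histone ChIP allelic-imbalance probes for a cohort
#'
#' Generates per-mark ChIP probe tables over the cohort's genes, with mean
#' |AI| set per expression class (silenced genes carry the strongest allelic
#' chromatin imbalance, PAR1-range escapees the weakest) and gene bodies
#' receiving `chip_body_factor` times as many probes as the +/-1 kb promoter
#' window. Expression classes are derived from the generator's true Xi
#' levels, so [chip_class_compare()] can be validated against the configured
#' means.
#'
#' @param cohort An `xci_cohort` from [simulate_cohort()].
#' @param config Defaults to the cohort's own config.
#' @return Tibble in the probe-table schema with `channel = "chip:<mark>"`,
#'   plus a `region` attribute-free layout (region is recovered from
#'   coordinates downstream); the true class per gene is attached as the
#'   attribute `"chip_truth"`.
#' @export
simulate_chip <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "xci_cohort"))
  with_seed(config$seed + 1L, simulate_chip_impl(cohort, config))
}

simulate_chip_impl <- function(cohort, cfg) {
  genes <- cohort$truth$genes
  # mean true xi per gene (variable genes: average of per-female draws)
  var_xi <- cohort$truth$gene_xi |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(mean_xi = mean(.data$true_xi))
  genes <- genes |>
    dplyr::left_join(var_xi, by = "gene") |>
    dplyr::mutate(mean_xi = dplyr::coalesce(.data$mean_xi, .data$true_xi))

  par1_min <- min(genes$mean_xi[genes$par1])
  genes$class <- dplyr::case_when(
    genes$true_status == "escape" & genes$mean_xi >= par1_min ~
      "escape_in_PAR1_range",
    genes$true_status == "escape" ~ "escape_outside_PAR1_range",
    genes$true_status == "subject" & genes$mean_xi >= 0.05 ~ "subject_ge5",
    genes$true_status == "subject" ~ "subject_lt5",
    TRUE ~ NA_character_)
  classed <- genes[!is.na(genes$class), ]

  tss <- ifelse(classed$strand == "+", classed$start, classed$end)
  tes <- ifelse(classed$strand == "+", classed$end, classed$start)
  n_body <- cfg$chip_body_factor

  per_gene <- function(i) {
    prom_pos <- round(stats::runif(1, tss[i] - 999, tss[i] + 999))
    body_pos <- round(stats::runif(n_body, min(tss[i], tes[i]),
                                   max(tss[i], tes[i])))
    tibble::tibble(gene = classed$gene[i],
                   pos = as.integer(c(prom_pos, body_pos)),
                   class = classed$class[i])
  }
  layout <- purrr::list_rbind(lapply(seq_len(nrow(classed)), per_gene))
  layout$probe_id <- sprintf("pC%05d", seq_len(nrow(layout)))

  samples <- sprintf("CHIP_F%02d", seq_len(cfg$n_chip_samples))
  out <- tidyr::expand_grid(mark = cfg$chip_marks,
                            sample_id = samples,
                            probe_id = layout$probe_id) |>
    dplyr::left_join(layout, by = "probe_id")
  n <- nrow(out)
  ai <- pmin(pmax(stats::rnorm(n, cfg$chip_class_means[out$class],
                               cfg$chip_sd), 0), 0.5)
  out <- out |>
    dplyr::transmute(
      probe_id = .data$probe_id,
      gene = .data$gene,
      chrom = "chrX",
      pos = .data$pos,
      sample_id = .data$sample_id,
      sex = "F",
      sample_set = unname(cohort$config$sample_sets[1]),
      informative = TRUE,
      intensity = round(stats::rlnorm(n, cohort$config$intensity_meanlog,
                                      cohort$config$intensity_sdlog), 2),
      frac_cdna = round(0.5 + sample(c(-1, 1), n, replace = TRUE) * ai, 6),
      frac_gdna = 0.5,
      channel = paste0("chip:", .data$mark))
  attr(out, "chip_truth") <- dplyr::select(classed, "gene", "class")
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
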