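#' Simulate a stage-structured embryo expression experiment
#'
#' Draws gene-by-sample negative-binomial read counts for a PG/AG (optionally
#' biparental) embryo series over the 4-cell, 8-cell and morula stages with an
#' injected maternal-to-zygotic program of known truth:
#'
#' * ZGA genes sit at a low pre-activation mean and jump `zga_fold`-fold at
#'   activation — the 8-cell stage for AG/biparental samples, delayed to the
#'   morula for PG samples;
#' * maternal-decay genes start high at the 4-cell stage and drop
#'   `decay_fold`-fold once ZGA has fired (8-cell in AG/biparental, morula in
#'   PG — decay requires the new transcriptional program);
#' * alpha-amanitin-treated 8-cell samples (if configured) keep ZGA genes at
#'   the pre-activation mean and retain maternal transcripts;
#' * stable genes keep one log-normal mean throughout.
#'
#' Per sample, programmed means are rescaled to an expected library of
#' `library_size` reads and counts drawn with `Var = mu + phi * mu^2`
#' (Poisson when `phi = 0`). Generation is deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_expression`:
#' \describe{
#'   \item{counts}{tibble, `gene_id` plus one integer column per sample.}
#'   \item{samples}{sample sheet tibble: `sample_id`, `stage`, `genotype`,
#'     `treatment`, `replicate`.}
#'   \item{genes}{tibble `gene_id`, `chrom`, `length_bp`.}
#'   \item{truth}{tibble `gene_id`, `class` (zga / maternal_decay / stable).}
#'   \item{programmed_mu}{tibble of the library-scaled expected count per
#'     gene per sample (for calibration checks; never an analysis input).}
#' }
#' @examples
#' sim <- simulate_expression(sim_config(seed = 1, n_genes = 100))
#' dplyr::count(sim$truth, class)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(sim_seed(config, 101L), {
    n <- config$n_genes
    n_zga <- round(config$frac_zga * n)
    n_dec <- round(config$frac_decay * n)
    class_vec <- rep("stable", n)
    if (n_zga > 0) class_vec[seq_len(n_zga)] <- "zga"
    if (n_dec > 0) class_vec[n_zga + seq_len(n_dec)] <- "maternal_decay"
    gene_id <- sprintf("G%05d", seq_len(n))

    genes <- tibble::tibble(
      gene_id = gene_id,
      chrom = ifelse(stats::runif(n) < config$frac_chrx, "chrX", config$chrom),
      length_bp = round(stats::runif(n, config$gene_length_range[1],
                                     config$gene_length_range[2]))
    )

    samples <- expand.grid(
      replicate = seq_len(config$n_rep),
      stage = c("4C", "8C", "morula"),
      genotype = config$genotypes,
      stringsAsFactors = FALSE
    )
    samples$treatment <- "none"
    if (config$n_rep_amanitin > 0) {
      am <- expand.grid(
        replicate = seq_len(config$n_rep_amanitin),
        stage = "8C",
        genotype = config$genotypes,
        stringsAsFactors = FALSE
      )
      am$treatment <- "amanitin"
      samples <- rbind(samples, am)
    }
    samples <- tibble::as_tibble(samples[, c("stage", "genotype", "treatment",
                                             "replicate")])
    samples$sample_id <- with(samples, paste0(
      genotype, "_", stage,
      ifelse(treatment == "none", "", paste0("_", treatment)), "_r", replicate))
    samples <- samples[, c("sample_id", "stage", "genotype", "treatment",
                           "replicate")]

    base_stable <- stats::rlnorm(n, config$stable_mu_meanlog, config$stable_mu_sdlog)
    mu_one <- function(stage, genotype, treatment) {
      # activation stage of the injected ZGA program for this sample
      act <- if (genotype == "PG") c("morula") else c("8C", "morula")
      active <- stage %in% act && treatment != "amanitin"
      mu <- base_stable
      is_z <- class_vec == "zga"
      mu[is_z] <- if (active) config$zga_mu_pre * config$zga_fold else config$zga_mu_pre
      is_d <- class_vec == "maternal_decay"
      mu[is_d] <- if (active) config$decay_mu_high / config$decay_fold else config$decay_mu_high
      mu * config$library_size / sum(mu)
    }
    mu_mat <- vapply(seq_len(nrow(samples)), function(i) {
      mu_one(samples$stage[i], samples$genotype[i], samples$treatment[i])
    }, numeric(n))
    colnames(mu_mat) <- samples$sample_id

    draw <- function(mu) {
      if (config$nb_dispersion == 0) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    }
    counts <- apply(mu_mat, 2, draw)
    counts_tbl <- tibble::as_tibble(as.data.frame(counts))
    counts_tbl <- dplyr::bind_cols(tibble::tibble(gene_id = gene_id), counts_tbl)

    structure(list(
      counts = counts_tbl,
      samples = samples,
      genes = genes,
      truth = tibble::tibble(gene_id = gene_id, class = class_vec),
      programmed_mu = dplyr::bind_cols(tibble::tibble(gene_id = gene_id),
                                       tibble::as_tibble(as.data.frame(mu_mat)))
    ), class = "sim_expression")
  })
}

#' Simulate parental allelic read counts
#'
#' Per gene, draws an informative-read depth
#' `n_g = depth_min + Poisson(depth_mean - depth_min)` and paternal reads
#' `Binomial(n_g, p)` with `p = 0.5` for biallelic genes, `p = pi` for
#' paternally biased genes and `p = 1 - pi` for maternally biased genes.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_allelic` with `counts` (tibble `gene_id`,
#'   `paternal_reads`, `maternal_reads`) and `truth` (tibble `gene_id`,
#'   `label` in biallelic/paternal/maternal).
#' @examples
#' sim <- simulate_allelic_counts(sim_config(seed = 1, n_allelic_genes = 50))
#' head(sim$counts)
#' @export
simulate_allelic_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(sim_seed(config, 202L), {
    n <- config$n_allelic_genes
    n_pat <- round(config$frac_paternal * n)
    n_mat <- round(config$frac_maternal * n)
    label <- rep("biallelic", n)
    if (n_pat > 0) label[seq_len(n_pat)] <- "paternal"
    if (n_mat > 0) label[n_pat + seq_len(n_mat)] <- "maternal"
    p <- c(biallelic = 0.5, paternal = config$allelic_pi,
           maternal = 1 - config$allelic_pi)[label]
    depth <- config$depth_min +
      stats::rpois(n, config$depth_mean - config$depth_min)
    depth <- pmax(depth, 1)
    pat <- stats::rbinom(n, depth, p)
    gene_id <- sprintf("A%05d", seq_len(n))
    list(
      counts = tibble::tibble(gene_id = gene_id, paternal_reads = pat,
                              maternal_reads = depth - pat),
      truth = tibble::tibble(gene_id = gene_id, label = unname(label))
    ) |> structure(class = "sim_allelic")
  })
}
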