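#' Parameters for the RNA-seq count simulator
#'
#' @param n_reps replicates per condition (>= 2; the study design is
#'   triplicate).
#' @param baseline_mean per-feature baseline mean counts in wild type. Either
#'   `NULL` (drawn log-normally with `baseline_meanlog`/`baseline_sdlog`), a
#'   scalar, or a vector named by feature id.
#' @param dispersion negative-binomial dispersion (variance = mu + dispersion
#'   * mu^2); must be > 0. Use a very small value to emulate the
#'   near-Poisson limit.
#' @param log2fc_map named numeric vector: planted knockout log2 fold changes
#'   per feature id (features not listed are null).
#' @param seed integer seed.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters used when
#'   `baseline_mean` is `NULL`.
#' @return a validated list of class `expr_sim_params`.
#' @export
expr_sim_params <- function(n_reps = 3L, baseline_mean = NULL,
                            dispersion = 0.1, log2fc_map = NULL, seed = 1L,
                            baseline_meanlog = log(200), baseline_sdlog = 1) {
  if (n_reps < 2) stop_fmt("n_reps must be >= 2")
  if (dispersion <= 0) stop_fmt("dispersion must be > 0")
  if (!is.null(baseline_mean) && any(baseline_mean < 0))
    stop_fmt("baseline_mean must be non-negative")
  structure(list(
    n_reps = as.integer(n_reps), baseline_mean = baseline_mean,
    dispersion = dispersion, log2fc_map = log2fc_map, seed = as.integer(seed),
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog
  ), class = "expr_sim_params")
}

#' Simulate a WT vs KO RNA-seq count experiment with planted fold changes
#'
#' Draws negative-binomial counts for the transposon and gene entries of the
#' catalog, with KO means scaled by `2^log2fc` for features listed in
#' `log2fc_map`. The same seed reproduces the matrix exactly.
#'
#' @param catalog a `reference_catalog`; transposon and gene entries become the
#'   simulated features (their lengths feed TPM computation downstream).
#' @param params an `expr_sim_params` object.
#' @return list with `counts` (features x samples integer matrix; columns
#'   `WT_1..n`, `KO_1..n`), `features` (data.frame `id`, `class`, `length`),
#'   `samples` (data.frame `sample`, `genotype`, `replicate`) and `truth`
#'   (data.frame `id`, `log2fc`).
#' @export
simulate_expression_experiment <- function(catalog, params) {
  catalog <- validate_catalog(catalog)
  if (!inherits(params, "expr_sim_params"))
    stop_fmt("params must come from expr_sim_params()")
  feats <- catalog[catalog$class %in% c("transposon", "gene"), , drop = FALSE]
  if (nrow(feats) == 0) stop_fmt("catalog has no transposon or gene features")

  withr::with_seed(params$seed, {
    g <- nrow(feats)
    base <- params$baseline_mean
    if (is.null(base)) {
      base <- stats::rlnorm(g, params$baseline_meanlog, params$baseline_sdlog)
    } else if (length(base) == 1L) {
      base <- rep(base, g)
    } else {
      if (is.null(names(base)) || !all(feats$id %in% names(base)))
        stop_fmt("vector baseline_mean must be named by feature id")
      base <- base[feats$id]
    }
    if (any(base < 0)) stop_fmt("baseline_mean must be non-negative")

    lfc <- stats::setNames(rep(0, g), feats$id)
    if (!is.null(params$log2fc_map) && length(params$log2fc_map)) {
      bad <- setdiff(names(params$log2fc_map), feats$id)
      if (length(bad)) stop_fmt("log2fc_map names not in catalog: %s",
                                paste(head(bad, 5), collapse = ", "))
      lfc[names(params$log2fc_map)] <- params$log2fc_map
    }

    n <- params$n_reps
    size <- 1 / params$dispersion
    mu_wt <- matrix(base, g, n)
    mu_ko <- matrix(base * 2^lfc, g, n)
    counts <- cbind(
      matrix(stats::rnbinom(g * n, size = size, mu = mu_wt), g, n),
      matrix(stats::rnbinom(g * n, size = size, mu = mu_ko), g, n)
    )
    dimnames(counts) <- list(feats$id,
                             c(sprintf("WT_%d", 1:n), sprintf("KO_%d", 1:n)))
    list(
      counts = counts,
      features = data.frame(id = feats$id, class = feats$class,
                            length = feats$length, stringsAsFactors = FALSE),
      samples = data.frame(
        sample = colnames(counts),
        genotype = rep(c("WT", "KO"), each = n),
        replicate = rep(1:n, 2), stringsAsFactors = FALSE
      ),
      truth = data.frame(id = feats$id, log2fc = unname(lfc),
                         stringsAsFactors = FALSE)
    )
  })
}
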