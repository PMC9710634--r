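#' Run one federated PCA algorithm on a partition
#'
#' Programmatic dispatcher over the five algorithms. The partition is assumed
#' centered (use [center_scale()] first); `k_prime` applies to the AP
#' methods, `epsilon`/`max_iter`/`seed` to subspace iteration.
#'
#' @param partition A centered [site_partition()].
#' @param algorithm One of `"p-cov"`, `"ap-cov"`, `"ap-stack"`, `"qr-pca"`,
#'   `"sub-it"`.
#' @param k Number of components.
#' @param k_prime Intermediate dimensionality for the AP methods; default
#'   `max(2k, k + 5)`.
#' @param epsilon,max_iter,seed Subspace-iteration controls (see [sub_it()]).
#' @param log Optional [comm_log()].
#' @return A [subspace()].
#' @export
federated_pca <- function(partition, algorithm, k, k_prime = NULL,
                          epsilon = 1e-9, max_iter = 1000L, seed = 0L,
                          log = NULL) {
  algorithm <- match.arg(algorithm,
                         c("p-cov", "ap-cov", "ap-stack", "qr-pca", "sub-it"))
  switch(algorithm,
         "p-cov" = p_cov(partition, k, log = log),
         "ap-cov" = ap_cov(partition, k, k_prime = k_prime, log = log),
         "ap-stack" = ap_stack(partition, k, k_prime = k_prime, log = log),
         "qr-pca" = qr_pca(partition, k, log = log),
         "sub-it" = sub_it(partition, k, epsilon = epsilon,
                           max_iter = max_iter, seed = seed, log = log))
}

#' Validated configuration of a pipeline run
#'
#' Bundles and validates everything [fedpca_run()] needs. Algorithm-specific
#' requirements are enforced here: the AP methods get a `k_prime` (defaulted
#' if missing), subspace iteration gets `epsilon` and `max_iter`.
#'
#' @param input Path to the data matrix (TSV/CSV).
#' @param algorithm `"p-cov"`, `"ap-cov"`, `"ap-stack"`, `"qr-pca"`,
#'   `"sub-it"`, or `"all"`.
#' @param k Number of components, `>= 1`.
#' @param output Output directory (created if needed).
#' @param sites Optional site-assignment TSV; when `NULL`, `site_sizes`
#'   must give the split.
#' @param site_sizes Optional integer sizes for [split_by_sizes()].
#' @param k_prime,epsilon,max_iter,seed See [federated_pca()].
#' @param center,scale Federated preprocessing flags; both default `TRUE`
#'   (the expression-data convention).
#' @param orientation,sep Input layout, see [read_matrix()].
#' @param against_centralized Also compute the centralized reference and an
#'   accuracy report? Default `TRUE`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, algorithm, k, output,
                       sites = NULL, site_sizes = NULL,
                       k_prime = NULL, epsilon = 1e-9, max_iter = 1000L,
                       seed = 0L, center = TRUE, scale = TRUE,
                       orientation = "samples-rows", sep = "\t",
                       against_centralized = TRUE) {
  algorithm <- match.arg(algorithm,
                         c("p-cov", "ap-cov", "ap-stack", "qr-pca", "sub-it",
                           "all"))
  if (!.is_count(k)) .stopf("`k` must be a positive integer")
  if (algorithm %in% c("ap-cov", "ap-stack", "all") && is.null(k_prime))
    k_prime <- max(2L * k, k + 5L)
  if (!is.null(k_prime) && (!.is_count(k_prime) || k_prime < k))
    .stopf("`k_prime` must be an integer >= k (got %s)", deparse(k_prime))
  if (!(is.numeric(epsilon) && length(epsilon) == 1L && epsilon > 0))
    .stopf("`epsilon` must be a positive number")
  if (!.is_count(max_iter)) .stopf("`max_iter` must be a positive integer")
  if (is.null(sites) && is.null(site_sizes))
    .stopf("either a site-assignment file (`sites`) or `site_sizes` is required")
  orientation <- match.arg(orientation, c("samples-rows", "features-rows"))
  structure(list(input = input, algorithm = algorithm, k = as.integer(k),
                 output = output, sites = sites, site_sizes = site_sizes,
                 k_prime = k_prime, epsilon = epsilon,
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 center = isTRUE(center), scale = isTRUE(scale),
                 orientation = orientation, sep = sep,
                 against_centralized = isTRUE(against_centralized)),
            class = "run_config")
}

.run_one <- function(algorithm, partition, A_pooled, config, outdir) {
  log <- comm_log()
  res <- withCallingHandlers(
    federated_pca(partition, algorithm, config$k, k_prime = config$k_prime,
                  epsilon = config$epsilon, max_iter = config$max_iter,
                  seed = config$seed, log = log),
    warning = function(w) {
      message("note [", algorithm, "]: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  tag <- gsub("-", "_", algorithm)
  write_subspace(res,
                 file.path(outdir, paste0(tag, "_eigenvectors.tsv")),
                 file.path(outdir, paste0(tag, "_eigenvalues.tsv")))
  proj <- unsplit_partition(partition) %*% res$vectors
  colnames(proj) <- paste0("PC", seq_len(config$k))
  write_matrix(proj, file.path(outdir, paste0(tag, "_projections.tsv")))
  write_comm_log(log, file.path(outdir, paste0(tag, "_commlog.json")))

  report <- list(algorithm = algorithm, k = config$k, seed = config$seed,
                 converged = res$converged %||% TRUE,
                 iterations = res$iterations %||% 1L,
                 eigenvalues = res$values,
                 comm_total = comm_total(log),
                 comm_rounds = comm_rounds(log))
  if (config$against_centralized) {
    ref <- centralized_pca(A_pooled, config$k)
    acc <- compare_subspaces(res, ref, A_pooled)
    report$accuracy <- list(
      per_eigenvector_angles_deg = acc$angles_deg,
      max_angle_deg = acc$max_angle,
      mean_angle_deg = acc$mean_angle,
      reconstruction_error_fed = acc$reconstruction_error_fed,
      reconstruction_error_ref = acc$reconstruction_error_ref,
      reconstruction_ratio = acc$ratio)
  }
  pred <- predicted_comm_cost(algorithm, d = length(partition$feature_ids),
                              k = config$k, n_sites = n_sites(partition),
                              k_prime = config$k_prime,
                              iterations = res$iterations %||% 1L,
                              site_sizes = site_sizes(partition))
  report$cost_prediction <- list(
    per_client_upload = pred$per_client_upload,
    per_client_download = pred$per_client_download,
    rounds = pred$rounds, total = pred$total)
  jsonlite::write_json(report, file.path(outdir, paste0(tag, "_report.json")),
                       auto_unbox = TRUE, digits = NA)
  report
}

#' Execute a configured federated PCA pipeline
#'
#' Reads the matrix, partitions it, runs the federated centering/scaling
#' protocol, executes the requested algorithm(s) and writes all artifacts to
#' the output directory: eigenvector/eigenvalue/projection TSVs, a
#' communication-log JSON, a per-algorithm report JSON (accuracy vs the
#' centralized reference plus the predicted communication cost) and a
#' `run_log.json` echoing the configuration. Identical config and seed give
#' identical artifacts.
#'
#' @param config A [run_config()].
#' @return Invisibly, the list of per-algorithm reports.
#' @export
fedpca_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output, showWarnings = FALSE, recursive = TRUE)
  A <- read_matrix(config$input, orientation = config$orientation,
                   sep = config$sep)
  partition <- if (!is.null(config$sites)) {
    partition_by_assignment(A, read_site_assignments(config$sites))
  } else {
    if (sum(config$site_sizes) != nrow(A))
      .stopf("site sizes sum to %d but the matrix has %d samples",
             sum(config$site_sizes), nrow(A))
    split_by_sizes(A, config$site_sizes)
  }
  if (config$center)
    partition <- center_scale(partition, scale = config$scale)
  A_pooled <- unsplit_partition(partition)

  algos <- if (config$algorithm == "all")
    c("p-cov", "ap-cov", "ap-stack", "qr-pca", "sub-it") else config$algorithm
  reports <- lapply(algos, .run_one, partition = partition,
                    A_pooled = A_pooled, config = config,
                    outdir = config$output)
  names(reports) <- algos
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("fedpca")),
         r_version = R.version.string,
         config = unclass(config)),
    file.path(config$output, "run_log.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(reports)
}

#' Simulate a dataset for federated PCA experiments
#'
#' Writes a synthetic expression-like matrix (TSV), a skewed site-assignment
#' table (TSV) and a provenance JSON with every generator parameter.
#'
#' @param output Output directory.
#' @param n,d Dimensions.
#' @param leading_values Planted singular-value scales (see
#'   [generate_lowrank()]).
#' @param noise_sd Noise level.
#' @param n_sites,alpha,min_size Site-size controls (see
#'   [skewed_site_sizes()]).
#' @param batch_shift Per-site mean-shift scale; 0 disables batch effects.
#' @param seed Master seed; sub-seeds are derived from it.
#' @return Invisibly, a list with the written paths.
#' @export
fedpca_simulate <- function(output, n = 300L, d = 1000L,
                            leading_values = NULL,
                            noise_sd = 0.5, n_sites = 12L, alpha = 0.3,
                            min_size = 1L, batch_shift = 0, seed = 0L) {
  dir.create(output, showWarnings = FALSE, recursive = TRUE)
  # default: the rank-15 spectrum 20..6, truncated so it stays feasible for
  # small matrices
  if (is.null(leading_values))
    leading_values <- utils::head(seq(20, 6, by = -1),
                                  max(1L, min(n, d) - 2L))
  A <- generate_lowrank(n, d, leading_values, noise_sd = noise_sd,
                        seed = seed)
  sizes <- skewed_site_sizes(n, n_sites, alpha = alpha, min_size = min_size,
                             seed = seed + 1L)
  partition <- split_by_sizes(A, sizes)
  if (batch_shift > 0)
    partition <- inject_batch_effects(partition, batch_shift, seed = seed + 2L)
  A_out <- unsplit_partition(partition)
  site_of <- integer(nrow(A_out))
  for (s in seq_along(partition$row_index))
    site_of[partition$row_index[[s]]] <- s
  paths <- list(matrix = file.path(output, "matrix.tsv"),
                sites = file.path(output, "sites.tsv"),
                provenance = file.path(output, "provenance.json"))
  write_matrix(A_out, paths$matrix)
  utils::write.table(
    data.frame(sample_id = rownames(A_out),
               site_id = sprintf("site_%02d", site_of)),
    paths$sites, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n = n, d = d, leading_values = leading_values, noise_sd = noise_sd,
         n_sites = n_sites, alpha = alpha, min_size = min_size,
         batch_shift = batch_shift, seed = seed, site_sizes = sizes),
    paths$provenance, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Compare two saved subspaces
#'
#' Loads two eigenvector/eigenvalue TSV pairs (see [write_subspace()]) plus
#' the data matrix they were computed on and writes an accuracy report JSON.
#'
#' @param input Data matrix TSV.
#' @param fed_vectors,fed_values Paths of the federated subspace.
#' @param ref_vectors,ref_values Paths of the reference subspace.
#' @param output Report JSON path.
#' @param orientation,sep See [read_matrix()].
#' @return Invisibly, the [compare_subspaces()] report.
#' @export
fedpca_evaluate <- function(input, fed_vectors, fed_values,
                            ref_vectors, ref_values, output,
                            orientation = "samples-rows", sep = "\t") {
  A <- read_matrix(input, orientation = orientation, sep = sep)
  s_fed <- read_subspace(fed_vectors, fed_values, method = "federated")
  s_ref <- read_subspace(ref_vectors, ref_values, method = "reference")
  acc <- compare_subspaces(s_fed, s_ref, A)
  jsonlite::write_json(unclass(acc), output, auto_unbox = TRUE, digits = NA)
  invisible(acc)
}

#' Privacy-aware resampled projection views
#'
#' Runs exact federated PCA (subspace iteration), projects every site
#' locally, resamples each site's projections from its Gaussian fit, and
#' writes one global TSV (`site_id`, `kind`, `PC1..PCk`) holding all exact
#' and all resampled points, plus one per-site view TSV containing that
#' site's exact points and only resampled points from the others.
#'
#' @param input Data matrix TSV.
#' @param sites Site-assignment TSV.
#' @param output Output directory.
#' @param k Number of components; default 2 (visualization).
#' @param m Resample size per site; default the site's own size.
#' @param seed Integer seed.
#' @param scale Scale to unit variance before PCA? Default `TRUE`.
#' @param orientation,sep See [read_matrix()].
#' @return Invisibly, the list of written paths.
#' @export
fedpca_resample <- function(input, sites, output, k = 2L, m = NULL,
                            seed = 0L, scale = TRUE,
                            orientation = "samples-rows", sep = "\t") {
  dir.create(output, showWarnings = FALSE, recursive = TRUE)
  A <- read_matrix(input, orientation = orientation, sep = sep)
  partition <- partition_by_assignment(A, read_site_assignments(sites))
  site_ids <- names(partition$sites) %||% as.character(seq_along(partition$sites))
  partition <- center_scale(partition, scale = scale)
  sub <- sub_it(partition, k, seed = seed)
  exact <- lapply(seq_along(partition$sites), function(s)
    project_onto(partition$sites[[s]], sub, site = site_ids[s]))
  resampled <- lapply(seq_along(exact), function(s)
    resample_local(exact[[s]], m = m, seed = seed + s))
  paths <- list(global = file.path(output, "projection_global.tsv"))
  global <- do.call(rbind, c(lapply(exact, .cloud_df),
                             lapply(resampled, .cloud_df)))
  utils::write.table(global, paths$global, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (s in seq_along(exact)) {
    view <- assemble_global_view(exact[[s]], resampled[-s])
    p <- file.path(output, sprintf("projection_view_%s.tsv", site_ids[s]))
    utils::write.table(view, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[paste0("view_", site_ids[s])]] <- p
  }
  invisible(paths)
}

.cloud_df <- function(cl) {
  cbind(data.frame(site_id = as.character(cl$site), kind = cl$kind,
                   stringsAsFactors = FALSE),
        as.data.frame(cl$points))
}
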