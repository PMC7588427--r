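#' Read an expression matrix
#'
#' Reads a genes-in-rows expression matrix from Matrix Market triplet format
#' (with sidecar gene/cell name files) or from dense CSV/TSV with gene names
#' in the first column and cell names in the header.
#'
#' @param path file path (`.mtx`, `.csv`, `.tsv`/`.txt`).
#' @param format `"auto"` (by extension), `"mtx"`, `"csv"` or `"tsv"`.
#' @param gene_file,cell_file sidecar name files for `.mtx` input (one name
#'   per line). Defaults to `<stem>_genes.txt` / `<stem>_cells.txt` next to
#'   the matrix.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                            gene_file = NULL, cell_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv",
                     tsv = , txt = "tsv",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    gene_file <- gene_file %||% paste0(stem, "_genes.txt")
    cell_file <- cell_file %||% paste0(stem, "_cells.txt")
    if (!file.exists(gene_file)) stop("gene name sidecar not found: ", gene_file)
    if (!file.exists(cell_file)) stop("cell name sidecar not found: ", cell_file)
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("malformed Matrix Market file: ",
                                           conditionMessage(e)))
    m <- as(m, "CsparseMatrix")
    genes <- readLines(gene_file)
    cells <- readLines(cell_file)
    expression_matrix(m, genes, cells)
  } else {
    df <- if (format == "csv") read.csv(path, row.names = 1,
                                        check.names = FALSE)
          else read.delim(path, row.names = 1, check.names = FALSE)
    expression_matrix(as.matrix(df), rownames(df), colnames(df))
  }
}

#' Read marker gene sets (GMT dialect)
#'
#' Parses a GMT file: one set per line, tab-separated
#' `name <tab> description <tab> gene [gene ...]`. A trailing `-` on a gene
#' token marks it as a negative marker; a trailing `+` is accepted and
#' stripped. Empty lines are skipped; a gene listed with both signs in one set
#' is a validation error.
#'
#' @param path GMT file path.
#' @return A list of [marker_set()] objects.
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) stop("marker file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line (need name, description, >= 1 gene): ", line)
    tokens <- parts[-(1:2)]
    tokens <- tokens[nzchar(tokens)]
    neg <- grepl("-$", tokens)
    genes <- sub("[+-]$", "", tokens)
    marker_set(parts[1], positive = genes[!neg], negative = genes[neg])
  })
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of every stage with their defaults. Any
#' subset can be overridden by a named nested list (e.g. parsed from a YAML
#' file).
#'
#' @param ... named overrides, e.g.
#'   `pipeline_config(reduction = list(dim = 30))`.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    reduction = list(dim = 50, seed = 0, z_limit = 10, oversampling = 10,
                     power_iter = 5),
    decomposition = list(k_min = 2, k_max = 30, tol = 1e-6, max_iter = 100,
                         nonzero_threshold = 1e-5),
    network = list(kappa = 1.0, backend = "exact", candidates = NULL),
    pruning = list(sig_threshold = 0.01, resolution = 2.0, seed = 0),
    layout = list(compactness = 50, epochs = 500, seed = 0,
                  negative_rate = 5, learning_rate = 1.0),
    annotation = list(alpha = 0.15, n_perm = 1000, ratio_threshold = 2.0,
                      seed = 0)
  )
  overrides <- list(...)
  if (length(overrides) == 1 && is.null(names(overrides)) &&
      is.list(overrides[[1]]))
    overrides <- overrides[[1]]
  for (nm in names(overrides)) {
    if (!nm %in% names(cfg)) stop("unknown configuration group: ", nm)
    cfg[[nm]] <- modifyList(cfg[[nm]], overrides[[nm]])
  }
  structure(cfg, class = "pipeline_config")
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[statescape] ", fmt), ...))
}

#' Run the full multiresolution pipeline
#'
#' Orchestrates kernel transform, rank-D reduction, multilevel decomposition,
#' network construction, multiresolution pruning, 2D/3D layout with de novo
#' colors, and (if marker sets are given) cell annotation. Per-stage timings
#' and parameters are logged to stderr.
#'
#' @param expr an [expression_matrix()] (or bare matrix of counts).
#' @param config a [pipeline_config()].
#' @param markers optional list of [marker_set()]s for annotation.
#' @param verbose log stage progress (default TRUE).
#' @return A list of class `statescape_bundle` with elements `reduction`,
#'   `multilevel`, `network`, `states`, `layout` (2D/3D embeddings + colors),
#'   optional `annotation`, plus `config` and `timings`.
#' @export
run_pipeline <- function(expr, config = pipeline_config(), markers = NULL,
                         verbose = TRUE) {
  expr <- as_expr_matrix(expr)
  stopifnot(inherits(config, "pipeline_config"))
  timings <- c()
  tick <- function(stage, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(code)
    dt <- proc.time()[["elapsed"]] - t0
    timings[[stage]] <<- dt
    stage_log(verbose, "%s done in %.2fs", stage, dt)
    out
  }

  rd <- config$reduction
  dim_eff <- min(rd$dim, min(dim(expr$values)) - 1)
  if (dim_eff < rd$dim)
    stage_log(verbose, "reduction dim clamped to %d", dim_eff)
  Z <- tick("transform", kernel_transform(expr, z_limit = rd$z_limit))
  red <- tick("reduce", reduce_profile(Z, dim = dim_eff, seed = rd$seed,
                                       oversampling = rd$oversampling,
                                       power_iter = rd$power_iter))
  dc <- config$decomposition
  # resolutions are capped by the reduced rank (SPA can select at most D
  # linearly independent prototypes)
  k_hi <- min(dc$k_max, red$D, ncol(red$S_r))
  if (k_hi < dc$k_max)
    stage_log(verbose, "k_max clamped to the reduced rank (%d)", k_hi)
  ml <- tick("multilevel", run_multilevel(red, k_min = dc$k_min,
                                          k_max = k_hi,
                                          max_iter = dc$max_iter,
                                          tol = dc$tol))
  nw <- config$network
  net <- tick("network", build_network(ml, kappa = nw$kappa,
                                       backend = nw$backend,
                                       candidates = nw$candidates))
  pr <- config$pruning
  states <- tick("prune", prune_multilevel(ml, sig_threshold = pr$sig_threshold,
                                           resolution = pr$resolution,
                                           seed = pr$seed,
                                           threshold = dc$nonzero_threshold))
  ly <- config$layout
  emb2 <- tick("layout2d", embed_network(net, dims = 2,
                                         compactness = ly$compactness,
                                         epochs = ly$epochs, seed = ly$seed,
                                         negative_rate = ly$negative_rate,
                                         learning_rate = ly$learning_rate))
  emb3 <- tick("layout3d", embed_network(net, dims = 3,
                                         compactness = ly$compactness,
                                         epochs = ly$epochs, seed = ly$seed,
                                         negative_rate = ly$negative_rate,
                                         learning_rate = ly$learning_rate))
  colors <- denovo_colors(emb3)

  annotation <- NULL
  if (!is.null(markers)) {
    an <- config$annotation
    annotation <- tick("annotate",
                       annotate_cells(expr, net, markers,
                                      n_perm = an$n_perm, seed = an$seed,
                                      alpha = an$alpha))
  }

  structure(list(reduction = red, multilevel = ml, network = net,
                 states = states,
                 layout = list(embedding2d = emb2, embedding3d = emb3,
                               colors = colors),
                 annotation = annotation,
                 config = config, timings = timings),
            class = "statescape_bundle")
}

#' @method print statescape_bundle
#' @export
print.statescape_bundle <- function(x, ...) {
  cat("<statescape_bundle>\n")
  cat(sprintf("  cells: %d  reduced rank: %d\n",
              length(x$reduction$cell_names), x$reduction$D))
  cat(sprintf("  multilevel patterns: %d  multiresolution states: %d\n",
              x$multilevel$T, nrow(x$states$selected)))
  invisible(x)
}

#' Write a results bundle to a portable container
#'
#' Serializes the main pipeline outputs as a directory of named plain-text
#' datasets (CSV matrices plus a JSON manifest): cell coordinates with RGB
#' colors, the multiresolution encoding `H_mr`, the selected representatives,
#' per-cell labels when annotation is present, and the configuration.
#'
#' @param bundle a `statescape_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "statescape_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  co <- as.data.frame(bundle$layout$embedding2d)
  col3 <- bundle$layout$colors
  co$r <- col3[, 1]; co$g <- col3[, 2]; co$b <- col3[, 3]
  write.csv(co, file.path(dir, "coordinates.csv"), row.names = FALSE)
  write.csv(as.data.frame(t(bundle$states$H_mr)),
            file.path(dir, "H_mr.csv"))
  write.csv(bundle$states$selected, file.path(dir, "representatives.csv"),
            row.names = FALSE)
  if (!is.null(bundle$annotation))
    write.csv(as.data.frame(bundle$annotation),
              file.path(dir, "labels.csv"), row.names = FALSE)
  manifest <- list(
    datasets = list.files(dir, pattern = "\\.csv$"),
    n_cells = length(bundle$reduction$cell_names),
    n_states = nrow(bundle$states$selected),
    T = bundle$multilevel$T,
    config = unclass(bundle$config),
    timings = as.list(bundle$timings))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}

#' Read a results bundle container
#'
#' Reads back the plain-text container written by [write_bundle()].
#'
#' @param dir container directory.
#' @return A list with `coordinates`, `H_mr`, `representatives`, optional
#'   `labels`, and the `manifest`.
#' @export
read_bundle <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("not a bundle directory (missing manifest.json)")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  out <- list(
    coordinates = read.csv(file.path(dir, "coordinates.csv")),
    H_mr = t(as.matrix(read.csv(file.path(dir, "H_mr.csv"), row.names = 1))),
    representatives = read.csv(file.path(dir, "representatives.csv")),
    manifest = manifest)
  lf <- file.path(dir, "labels.csv")
  if (file.exists(lf)) out$labels <- read.csv(lf)
  out
}
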