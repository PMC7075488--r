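# Readers and writers for instrument summaries, results tables and
# synthetic fixtures. Instrument files are JSON (single document) or a
# pair of CSVs (dimensions table + labeled correlation matrix).

#' Read an instrument summary from disk
#'
#' JSON layout (single file):
#' \preformatted{
#' {"schema_version": 1,
#'  "dimensions": [{"name": "...", "alpha": 0.8, "n_items": 4}, ...],
#'  "composite_corr": [[1, r12, ...], [r12, 1, ...], ...]}
#' }
#' CSV layout (two files): a dimensions table with columns
#' `name, alpha, n_items`, and a correlation matrix with a header row and a
#' leading label column, both label sets matching the dimension names in
#' order. Validation failures name the offending dimension/entries;
#' asymmetry beyond 1e-6 is an error, below it the matrix is symmetrized
#' by averaging.
#'
#' @param path Path to the JSON file, or to the dimensions CSV.
#' @param matrix_path Path to the correlation-matrix CSV (CSV layout only).
#' @return An [instrument_summary()].
#' @export
read_instrument <- function(path, matrix_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(doc$dimensions) || is.null(doc$composite_corr)) {
      stop("instrument JSON needs 'dimensions' and 'composite_corr' fields",
           call. = FALSE)
    }
    dd <- as.data.frame(doc$dimensions)
    r <- as.matrix(doc$composite_corr)
  } else {
    if (is.null(matrix_path)) {
      stop("CSV layout needs both a dimensions file and matrix_path",
           call. = FALSE)
    }
    dd <- utils::read.csv(path, stringsAsFactors = FALSE)
    rm_df <- utils::read.csv(matrix_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    labels <- rm_df[[1]]
    r <- as.matrix(rm_df[, -1, drop = FALSE])
    rownames(r) <- labels
    if (!identical(as.character(labels), colnames(r))) {
      stop("matrix row labels do not match its column header", call. = FALSE)
    }
  }
  need <- c("name", "alpha", "n_items")
  if (!all(need %in% names(dd))) {
    stop("dimensions table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dims <- lapply(seq_len(nrow(dd)), function(i) {
    dimension_summary(as.character(dd$name[i]), dd$alpha[i], dd$n_items[i])
  })
  if (!is.null(rownames(r)) && any(nzchar(rownames(r))) &&
      !identical(rownames(r), as.character(dd$name))) {
    stop("correlation-matrix labels must match dimension names in order",
         call. = FALSE)
  }
  instrument_summary(dims, r)
}

#' Write an instrument summary as JSON
#'
#' Inverse of [read_instrument()] (JSON layout); full numeric precision.
#'
#' @param instr An [instrument_summary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_instrument <- function(instr, path) {
  stopifnot(inherits(instr, "instrument_summary"))
  doc <- list(
    schema_version = 1L,
    dimensions = data.frame(
      name = vapply(instr$dimensions, `[[`, character(1), "name"),
      alpha = vapply(instr$dimensions, `[[`, numeric(1), "alpha"),
      n_items = vapply(instr$dimensions, `[[`, integer(1), "n_items"),
      stringsAsFactors = FALSE),
    composite_corr = unname(instr$composite_corr))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' Write assessment or simulation results to disk
#'
#' Accepts a `cell_results` table from [run_grid()], an
#' `instrument_assessment`, or any data.frame. CSV output keeps full
#' numeric precision (deterministic column order; round-trippable via
#' `read.csv`); JSON output uses full precision too.
#'
#' @param x Results object.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(x, "instrument_assessment")) x <- as.data.frame(x)
  if (!is.data.frame(x)) stop("x must be a data.frame-like object",
                              call. = FALSE)
  if (format == "csv") {
    utils::write.csv(x, path, row.names = FALSE)
  } else {
    jsonlite::write_json(x, path, digits = NA, dataframe = "rows")
  }
  invisible(path)
}

#' Read back a results table
#'
#' @param path File written by [write_results()].
#' @return A data.frame.
#' @export
read_results <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

#' Generate a synthetic instrument fixture with known population verdict
#'
#' Simulates one dataset from a two-factor model, summarizes it the way a
#' published article would (sample standardized alphas, item counts, and
#' the composite-score correlation matrix), writes the instrument JSON, and
#' records the noise-free population verdict alongside for reference.
#'
#' @param kind `"tau_equivalent"` (equal 0.70 loadings) or `"congeneric"`
#'   (the most heterogeneous default pattern, 0.45/0.70/0.95).
#' @param phi Latent correlation of the generating model.
#' @param n Sample size.
#' @param seed Integer seed (byte-reproducible output).
#' @param dir Output directory.
#' @param loadings Optional explicit loading vector overriding `kind`.
#' @return A list: `instrument_path`, `truth_path`, `instrument`
#'   (the `instrument_summary`), `population_verdict`.
#' @export
generate_fixture <- function(kind = c("tau_equivalent", "congeneric"),
                             phi, n, seed, dir = ".", loadings = NULL) {
  kind <- match.arg(kind)
  if (is.null(loadings)) {
    loadings <- if (kind == "tau_equivalent") c(0.7, 0.7, 0.7)
                else c(0.45, 0.70, 0.95)
  }
  model <- factor_model(loadings, loadings, phi)
  dat <- sample_dataset(model, n, seed = seed)
  kx <- length(loadings)
  r_all <- stats::cor(dat)
  alpha_x <- standardized_alpha(r_all[1:kx, 1:kx])
  alpha_y <- standardized_alpha(r_all[(kx + 1):(2 * kx), (kx + 1):(2 * kx)])
  r_comp <- stats::cor(rowMeans(dat[, 1:kx]),
                       rowMeans(dat[, (kx + 1):(2 * kx)]))
  instr <- instrument_summary(
    list(dimension_summary("dim_x", alpha_x, kx),
         dimension_summary("dim_y", alpha_y, kx)),
    matrix(c(1, r_comp, r_comp, 1), 2, 2))

  # noise-free verdict from population quantities
  alphas <- population_alphas(model)
  r_pop <- population_composite_correlation(model)
  pop <- assess_pair(dimension_summary("dim_x", alphas[1], kx),
                     dimension_summary("dim_y", alphas[2], kx), r_pop)

  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- sprintf("%s_phi%03d_n%d_seed%d", kind, round(100 * phi), n, seed)
  instrument_path <- file.path(dir, paste0(stem, ".json"))
  truth_path <- file.path(dir, paste0(stem, "_truth.json"))
  write_instrument(instr, instrument_path)
  jsonlite::write_json(
    list(kind = kind, loadings = loadings, phi = phi, n = n, seed = seed,
         population_verdict = pop$verdict,
         population_alphas = alphas, population_composite_corr = r_pop),
    truth_path, digits = NA, auto_unbox = TRUE)
  list(instrument_path = instrument_path, truth_path = truth_path,
       instrument = instr, population_verdict = pop$verdict)
}
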