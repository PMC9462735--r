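#' Read a beta matrix from tab-separated text
#'
#' Expects a header row of sample ids and a first column of CpG ids; values
#' are decimals in `[0, 1]` with `NA` for missing. Gzip-compressed files are
#' read transparently. Validation errors name the offending CpG or sample.
#'
#' @param path Path to a `.tsv` or `.tsv.gz` file.
#' @return Numeric matrix with CpG row names and sample column names.
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("beta matrix needs a CpG id column plus samples")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate CpG ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value out of [0, 1] at CpG %s, sample %s",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  m
}

#' Write a beta matrix as tab-separated text
#'
#' Values are written with 6 decimal places (well above array noise) so that
#' write-read round trips are identity at the printed precision.
#'
#' @param betas Numeric matrix with row and column names.
#' @param path Output path; a `.gz` suffix writes gzip-compressed.
#' @param digits Decimal places to print.
#' @return The path, invisibly.
#' @export
write_beta_matrix <- function(betas, path, digits = 6) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("cpg_id", colnames(betas)), collapse = "\t"), con)
  fmt <- formatC(betas, format = "f", digits = digits)
  fmt[is.na(betas)] <- "NA"
  body <- paste(rownames(betas),
                apply(fmt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a per-sample purity table
#'
#' Two-column tab-separated text (`sample_id`, `purity`); purity must lie in
#' `(0, 1]`.
#'
#' @param path Path to the file (header optional, detected by a non-numeric
#'   second field on the first line).
#' @return Named numeric purity vector.
#' @export
read_purity <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  header <- length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2])))
  df <- utils::read.delim(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("purity table needs two columns (sample_id, purity)")
  p <- as.numeric(df[[2]])
  names(p) <- as.character(df[[1]])
  if (anyDuplicated(names(p))) {
    stop("duplicate sample ids in purity table: ",
         paste(unique(names(p)[duplicated(names(p))]), collapse = ", "))
  }
  bad <- which(!is.finite(p) | p <= 0 | p > 1)
  if (length(bad) > 0) {
    stop("invalid purity (must be in (0, 1]) for sample(s): ",
         paste(names(p)[bad], collapse = ", "))
  }
  p
}

#' Write the outputs of a matrix adjustment
#'
#' Writes the purified-tumor and inferred-normal beta matrices, the
#' population label matrix, the per-CpG fit summary, and a JSON run manifest
#' (configuration, seed, package version) sufficient to reproduce the run
#' byte for byte.
#'
#' @param result A `beta_adjustment` from [adjust_matrix()].
#' @param dir Output directory, created if needed.
#' @param config Optional named list of run configuration stored in the
#'   manifest.
#' @return Named character vector of the files written, invisibly.
#' @export
write_outputs <- function(result, dir, config = list()) {
  stopifnot(inherits(result, "beta_adjustment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    tumor = file.path(dir, "tumor_beta.tsv"),
    normal = file.path(dir, "normal_beta.tsv"),
    populations = file.path(dir, "populations.tsv"),
    fit_summary = file.path(dir, "fit_summary.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_beta_matrix(result$tumor, paths[["tumor"]])
  write_beta_matrix(result$normal, paths[["normal"]])
  pops <- result$populations
  con <- file(paths[["populations"]], "w")
  writeLines(paste(c("cpg_id", colnames(pops)), collapse = "\t"), con)
  writeLines(paste(rownames(pops),
                   apply(pops, 1, paste, collapse = "\t"), sep = "\t"), con)
  close(con)
  utils::write.table(result$fit_summary, paths[["fit_summary"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "purebeta",
    version = as.character(utils::packageVersion("purebeta")),
    global_seed = result$global_seed,
    noise_sd = result$noise_sd,
    n_cpgs = nrow(result$tumor),
    n_samples = ncol(result$tumor),
    config = config
  )
  jsonlite::write_json(manifest, paths[["manifest"]],
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
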