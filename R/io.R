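#' Read a GCT expression matrix
#'
#' Parses the GCT 1.2 dialect: a `#1.2` version line, a `nrow<TAB>ncol`
#' dimension line, then a header `NAME<TAB>Description<TAB><sample ids>` and
#' one row per gene. Row descriptions are dropped.
#'
#' @param path path to a `.gct` file.
#' @return Numeric matrix (genes x samples) with dimnames.
#' @export
read_gct <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || !startsWith(lines[[1]], "#1.2")) {
    stop("not a GCT 1.2 file: ", path)
  }
  dims <- as.integer(strsplit(lines[[2]], "\t", fixed = TRUE)[[1]][1:2])
  tab <- utils::read.delim(text = lines[-(1:2)], check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(tab) != dims[[1]] || ncol(tab) - 2L != dims[[2]]) {
    stop("GCT dimension line disagrees with table body in ", path)
  }
  m <- as.matrix(tab[, -(1:2), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1]]
  m
}

#' Write a matrix as GCT 1.2
#'
#' @param m numeric matrix with dimnames (genes x samples).
#' @param path output path.
#' @param descriptions optional per-row description column (default `"na"`).
#' @return `path`, invisibly.
#' @export
write_gct <- function(m, path, descriptions = NULL) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  if (is.null(descriptions)) descriptions <- rep("na", nrow(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
  header <- paste(c("NAME", "Description", colnames(m)), collapse = "\t")
  body <- paste(rownames(m), descriptions,
                apply(m, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), con)
  invisible(path)
}

# Plain TSV with no quoting surprises; used for all tabular artifacts.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

# md5 of the effective (JSON-serialised) config; stamped into every output
# so re-runs are attributable without an external hashing dependency.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write an expression cohort as GCT plus donor-metadata TSV
#'
#' @param cohort an `expression_cohort`.
#' @param prefix output path prefix; writes `<prefix>.gct` and
#'   `<prefix>_donors.tsv` (donor, bracket, midpoint, tissue).
#' @return The GCT path, invisibly.
#' @export
write_cohort <- function(cohort, prefix) {
  stopifnot(inherits(cohort, "expression_cohort"))
  write_gct(cohort$matrix, paste0(prefix, ".gct"))
  meta <- cohort$brackets
  meta$tissue <- cohort$tissue
  write_tsv(meta, paste0(prefix, "_donors.tsv"))
  invisible(paste0(prefix, ".gct"))
}

#' Read an expression cohort from GCT plus donor-metadata TSV
#'
#' @param prefix path prefix used by [write_cohort()].
#' @return An `expression_cohort`.
#' @export
read_cohort <- function(prefix) {
  m <- read_gct(paste0(prefix, ".gct"))
  meta <- read_tsv(paste0(prefix, "_donors.tsv"))
  expression_cohort(m, tissue = meta$tissue[[1]],
                    brackets = meta[, c("donor", "bracket", "midpoint")])
}

#' Write a drug library as GCT plus compound-annotation TSV
#'
#' @param profiles a `drug_profile_matrix`.
#' @param prefix output path prefix; writes `<prefix>.gct` (compounds x
#'   genes) and `<prefix>_compounds.tsv`.
#' @return The GCT path, invisibly.
#' @export
write_drug_library <- function(profiles, prefix) {
  stopifnot(inherits(profiles, "drug_profile_matrix"))
  write_gct(profiles$z, paste0(prefix, ".gct"))
  write_tsv(profiles$annotations, paste0(prefix, "_compounds.tsv"))
  invisible(paste0(prefix, ".gct"))
}

#' Read a drug library from GCT plus compound-annotation TSV
#'
#' @param prefix path prefix used by [write_drug_library()].
#' @return A `drug_profile_matrix`.
#' @export
read_drug_library <- function(prefix) {
  drug_profile_matrix(read_gct(paste0(prefix, ".gct")),
                      read_tsv(paste0(prefix, "_compounds.tsv")))
}
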