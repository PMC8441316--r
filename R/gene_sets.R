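#' Gene-set collections for matrisome membership queries
#'
#' A `gene_set_collection` holds named gene sets (ordered character vectors),
#' an optional per-gene category label, and an optional measurement universe.
#' The master set `"matrisome"` is defined as the union of all category sets
#' and is (re)built automatically when categories are present.
#'
#' @param sets named list of character vectors (set name -> gene symbols).
#' @param categories optional named character vector (gene symbol -> category).
#' @param universe optional character vector of all measurable gene symbols.
#'
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets = list(), categories = NULL,
                                universe = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) && is.null(names(sets))) stop("sets must be named")
  sets <- lapply(sets, function(g) {
    g <- trimws(as.character(g))
    if (any(!nzchar(g))) stop("empty gene symbol in set")
    if (anyDuplicated(g)) stop("duplicate symbols within a set")
    g
  })
  categorized <- names(categories)
  if (length(categorized)) {
    in_some_set <- categorized %in% unlist(sets, use.names = FALSE)
    if (!all(in_some_set)) {
      stop("categorized genes absent from every set: ",
           paste(categorized[!in_some_set], collapse = ", "))
    }
    category_sets <- setdiff(names(sets), "matrisome")
    sets[["matrisome"]] <- unique(unlist(sets[category_sets],
                                         use.names = FALSE))
  }
  structure(list(sets = sets, categories = categories, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, %d genes in master matrisome\n",
              length(x$sets), length(matrisome_genes(x))))
  invisible(x)
}

#' Master matrisome membership of a collection
#'
#' @param coll a `gene_set_collection`.
#' @return Character vector of genes in the `"matrisome"` master set; if no
#'   master set is declared, the union of all sets.
#' @export
matrisome_genes <- function(coll) {
  stopifnot(inherits(coll, "gene_set_collection"))
  if ("matrisome" %in% names(coll$sets)) return(coll$sets[["matrisome"]])
  unique(unlist(coll$sets, use.names = FALSE))
}

#' Read gene sets from a GMT file
#'
#' GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Set order is preserved.
#' A line with fewer than two tab-separated fields is a parse error naming
#' the offending line.
#'
#' @param path path to a GMT file.
#' @return A `gene_set_collection` (no categories, no universe).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(gene_set_collection())
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2) {
      stop(sprintf("malformed GMT line %d: fewer than 2 tab fields", i))
    }
    genes <- trimws(fields[-(1:2)])
    sets[[trimws(fields[[1]])]] <- genes[nzchar(genes)]
  }
  gene_set_collection(sets)
}

#' Write gene sets to a GMT file
#'
#' @param coll a `gene_set_collection`.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions;
#'   defaults to `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path, descriptions = NULL) {
  stopifnot(inherits(coll, "gene_set_collection"))
  lines <- vapply(names(coll$sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else "na"
    paste(c(nm, desc, coll$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Partition a measured-gene universe into matrisome and background
#'
#' Splits the measured genes into those belonging to the master matrisome set
#' and the remaining background, mirroring the foreground/background split
#' used when scoring drug profiles for matrisome regulation.
#'
#' @param coll a `gene_set_collection`.
#' @param measured non-empty character vector of measured gene symbols.
#' @return List with `matrisome_measured`, `background` (both preserve the
#'   order of `measured`) and logical `empty_intersection`. The two parts are
#'   disjoint and their union is `measured`. An empty intersection raises a
#'   warning, not an error.
#' @export
partition_universe <- function(coll, measured) {
  stopifnot(inherits(coll, "gene_set_collection"))
  measured <- trimws(as.character(measured))
  if (!length(measured)) stop("measured must be non-empty")
  mat <- matrisome_genes(coll)
  in_mat <- measured %in% mat
  if (!any(in_mat)) warning("no measured gene belongs to the matrisome")
  list(matrisome_measured = measured[in_mat],
       background = measured[!in_mat],
       empty_intersection = !any(in_mat))
}

# Category labels mirroring the six divisions of the human matrisome.
matrisome_category_labels <- function() {
  c("collagens", "glycoproteins", "proteoglycans",
    "ECM-regulators", "secreted-factors", "ECM-affiliated")
}

#' Demo matrisome collection with the six canonical categories
#'
#' Builds a small synthetic stand-in for the human matrisome gene-set file:
#' `n_per_category` invented symbols per category (prefix encodes the
#' category), a master `"matrisome"` union set, and per-gene category labels.
#' Used by examples and tests; real analyses should load their own GMT.
#'
#' @param n_per_category genes per category set.
#' @return A `gene_set_collection`.
#' @export
demo_matrisome_collection <- function(n_per_category = 5) {
  labels <- matrisome_category_labels()
  prefix <- c("COL", "GP", "PG", "REG", "SF", "AFF")
  sets <- stats::setNames(lapply(seq_along(labels), function(i) {
    sprintf("%s%d", prefix[[i]], seq_len(n_per_category))
  }), labels)
  genes <- unlist(sets, use.names = FALSE)
  categories <- stats::setNames(rep(labels, each = n_per_category), genes)
  gene_set_collection(sets, categories = categories)
}
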