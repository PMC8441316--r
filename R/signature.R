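#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate control: with `p_(1) <= ... <= p_(n)`, the
#' adjusted value is `q_(i) = min_{j >= i} n * p_(j) / j` (capped at 1), and
#' a hypothesis is rejected iff its q-value is at or below `alpha`. The
#' step-up property means a small p-value late in the sorted order can
#' rescue earlier ranks.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return List with `q_values` (same order as input) and logical `reject`.
#' @export
bh_adjust <- function(p_values, alpha = 0.05) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  n <- length(p)
  if (!n) return(list(q_values = numeric(0), reject = logical(0)))
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  q <- numeric(n)
  q[o] <- q_sorted
  list(q_values = q, reject = q <= alpha)
}

#' Per-gene age association within a cohort
#'
#' Compares the old donor group against the young donor group gene by gene.
#' The absolute change is the difference of group means on the expression
#' scale (old minus young); the relative change divides that difference by
#' the young mean. Significance comes from Welch's t test on `log(x + 1)`
#' values, with q-values from [bh_adjust()] across the genes of the cohort
#' (i.e. per tissue). Direction is the sign of the absolute change for genes
#' passing the FDR threshold and `"none"` otherwise.
#'
#' @param cohort an `expression_cohort`.
#' @param young_brackets,old_brackets disjoint non-empty sets of bracket
#'   labels; defaults are the two youngest and the two oldest brackets
#'   present, in bracket order.
#' @param alpha FDR level for the direction call.
#' @return data.frame with columns gene, tissue, absolute_change,
#'   relative_change, p_value, q_value, direction. A zero young mean makes
#'   relative_change `NA` (gene excluded from relative rankings).
#' @export
compute_age_change <- function(cohort, young_brackets = NULL,
                               old_brackets = NULL, alpha = 0.05) {
  stopifnot(inherits(cohort, "expression_cohort"))
  br <- cohort$brackets
  ord <- unique(br$bracket[order(br$midpoint)])
  if (is.null(young_brackets)) young_brackets <- utils::head(ord, 2)
  if (is.null(old_brackets)) old_brackets <- utils::tail(ord, 2)
  if (!length(young_brackets) || !length(old_brackets)) {
    stop("bracket sets must be non-empty")
  }
  if (length(intersect(young_brackets, old_brackets))) {
    stop("young and old bracket sets overlap")
  }
  young <- br$bracket %in% young_brackets
  old <- br$bracket %in% old_brackets
  if (sum(young) < 2 || sum(old) < 2) stop("need >= 2 donors per group")

  x <- cohort$matrix
  m_young <- rowMeans(x[, young, drop = FALSE])
  m_old <- rowMeans(x[, old, drop = FALSE])
  absolute <- m_old - m_young
  relative <- ifelse(m_young > 0, absolute / m_young, NA_real_)

  ly <- log1p(x[, young, drop = FALSE])
  lo <- log1p(x[, old, drop = FALSE])
  p <- welch_t_rows(lo, ly)
  adj <- bh_adjust(p, alpha = alpha)
  direction <- ifelse(!adj$reject | absolute == 0, "none",
                      ifelse(absolute > 0, "up_with_age", "down_with_age"))
  data.frame(gene = rownames(x), tissue = cohort$tissue,
             absolute_change = unname(absolute),
             relative_change = unname(relative),
             p_value = unname(p), q_value = adj$q_values,
             direction = direction, stringsAsFactors = FALSE,
             row.names = NULL)
}

# Row-wise Welch t-test p-values (two-sided), vectorised over genes.
welch_t_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, stats::var); vb <- apply(b, 1L, stats::var)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  # zero-variance genes: certain difference, or no evidence at all
  zero <- se2 == 0
  p[zero] <- ifelse(ma[zero] == mb[zero], 1, 0)
  p[is.na(p)] <- 1
  p
}

#' Restrict age associations to matrisome genes
#'
#' @param assocs data.frame from [compute_age_change()].
#' @param coll a `gene_set_collection`.
#' @return The matrisome rows of `assocs`, order preserved.
#' @export
filter_matrisome <- function(assocs, coll) {
  assocs[assocs$gene %in% matrisome_genes(coll), , drop = FALSE]
}

#' Matreotype signature container
#'
#' @param entries data.frame with columns `gene`, `direction` (one of
#'   `up_with_age` / `down_with_age`) and `support` (source count).
#' @param conflicts character vector of genes excluded for direction ties.
#' @param kind `"aged"` or `"youthful"`.
#' @return A `matreotype_signature` object.
#' @export
matreotype_signature <- function(entries, conflicts = character(0),
                                 kind = c("aged", "youthful")) {
  kind <- match.arg(kind)
  stopifnot(all(c("gene", "direction", "support") %in% names(entries)))
  if (anyDuplicated(entries$gene)) stop("gene listed twice in signature")
  if (!all(entries$direction %in% c("up_with_age", "down_with_age"))) {
    stop("invalid direction label")
  }
  if (length(intersect(conflicts, entries$gene))) {
    stop("conflicted genes cannot also be entries")
  }
  rownames(entries) <- NULL
  structure(list(entries = entries, conflicts = conflicts, kind = kind),
            class = "matreotype_signature")
}

#' @export
print.matreotype_signature <- function(x, ...) {
  cat(sprintf("matreotype_signature (%s): %d genes (%d up, %d down), %d conflicts\n",
              x$kind, nrow(x$entries),
              sum(x$entries$direction == "up_with_age"),
              sum(x$entries$direction == "down_with_age"),
              length(x$conflicts)))
  invisible(x)
}

#' Build a multi-source consensus (aged) matreotype signature
#'
#' A gene enters the compendium when at least `min_sources` sources support
#' it. Direction is decided by strict majority among the sources that report
#' a direction; exact ties are excluded and recorded in `conflicts` (the
#' tissue-dependent behaviour seen for genes like GDF15 motivates exclusion
#' over arbitration). Sources reporting association without directionality
#' (`direction == "none"`) count toward support but not toward the vote; a
#' supported gene with no directional source at all is likewise excluded as
#' a conflict. The result is invariant to source ordering.
#'
#' @param per_source_signatures named list of data.frames, each with columns
#'   `gene` and `direction` (`up_with_age`, `down_with_age`, or `none`).
#' @param min_sources minimum number of supporting sources (default 3).
#' @return A `matreotype_signature` of kind `"aged"`.
#' @export
build_compendium <- function(per_source_signatures, min_sources = 3) {
  stopifnot(length(per_source_signatures) >= 1)
  src <- lapply(per_source_signatures, function(s) {
    stopifnot(all(c("gene", "direction") %in% names(s)))
    s <- s[s$direction %in% c("up_with_age", "down_with_age", "none"), ,
           drop = FALSE]
    s[!duplicated(s$gene), , drop = FALSE]
  })
  all_rows <- do.call(rbind, src)
  genes <- sort(unique(all_rows$gene))
  support <- table(factor(all_rows$gene, levels = genes))
  n_up <- table(factor(all_rows$gene[all_rows$direction == "up_with_age"],
                       levels = genes))
  n_dn <- table(factor(all_rows$gene[all_rows$direction == "down_with_age"],
                       levels = genes))
  supported <- support >= min_sources
  tie <- supported & (n_up == n_dn)   # includes the no-directional-source case
  keep <- supported & !tie
  direction <- ifelse(n_up > n_dn, "up_with_age", "down_with_age")
  matreotype_signature(
    data.frame(gene = genes[keep], direction = direction[keep],
               support = as.integer(support[keep]),
               stringsAsFactors = FALSE),
    conflicts = genes[tie], kind = "aged")
}

#' Invert a matreotype signature (aged <-> youthful)
#'
#' Flips every gene's direction and toggles the kind; support counts and the
#' conflict list are preserved. Self-inverse.
#'
#' @param sig a `matreotype_signature`.
#' @return The inverted `matreotype_signature`.
#' @export
invert_signature <- function(sig) {
  stopifnot(inherits(sig, "matreotype_signature"))
  entries <- sig$entries
  entries$direction <- ifelse(entries$direction == "up_with_age",
                              "down_with_age", "up_with_age")
  matreotype_signature(entries, conflicts = sig$conflicts,
                       kind = if (sig$kind == "aged") "youthful" else "aged")
}

#' Split a signature into its directional halves
#'
#' @param sig a `matreotype_signature`.
#' @return List with character vectors `up_with_age` and `down_with_age`;
#'   disjoint, and their union is the signature's gene set.
#' @export
split_signature <- function(sig) {
  stopifnot(inherits(sig, "matreotype_signature"))
  list(up_with_age = sig$entries$gene[sig$entries$direction == "up_with_age"],
       down_with_age = sig$entries$gene[sig$entries$direction == "down_with_age"])
}

#' Derive a per-source directional signature from age associations
#'
#' Helper mapping a [compute_age_change()] table to the `(gene, direction)`
#' source format consumed by [build_compendium()]. The inclusion channel
#' selects which change statistic must be available: `"absolute"` keeps all
#' FDR-significant genes, `"relative"` additionally requires a defined
#' relative change, `"union"` is the same as `"absolute"` here since the
#' relative channel is a subset whenever young means are positive.
#'
#' @param assocs data.frame from [compute_age_change()].
#' @param channel `"absolute"`, `"relative"` or `"union"`.
#' @return data.frame with columns `gene`, `direction` (significant genes
#'   only).
#' @export
associations_to_source <- function(assocs,
                                   channel = c("absolute", "relative",
                                               "union")) {
  channel <- match.arg(channel)
  keep <- assocs$direction != "none"
  if (channel == "relative") keep <- keep & !is.na(assocs$relative_change)
  data.frame(gene = assocs$gene[keep], direction = assocs$direction[keep],
             stringsAsFactors = FALSE)
}

#' Write / read a signature as TSV
#'
#' Columns: gene, direction, support, kind. Conflicts travel in a sidecar
#' file `<path>.conflicts.tsv` when present.
#'
#' @param sig a `matreotype_signature`.
#' @param path output TSV path.
#' @return `path` invisibly (write); a `matreotype_signature` (read).
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "matreotype_signature"))
  out <- sig$entries
  out$kind <- sig$kind
  write_tsv(out, path)
  if (length(sig$conflicts)) {
    write_tsv(data.frame(gene = sig$conflicts),
              paste0(path, ".conflicts.tsv"))
  }
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  tab <- read_tsv(path)
  conflicts_path <- paste0(path, ".conflicts.tsv")
  conflicts <- if (file.exists(conflicts_path)) {
    read_tsv(conflicts_path)$gene
  } else character(0)
  kind <- if (nrow(tab)) tab$kind[[1]] else "aged"
  matreotype_signature(tab[, c("gene", "direction", "support")],
                       conflicts = conflicts, kind = kind)
}
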