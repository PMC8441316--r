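#' Drug perturbation-profile container
#'
#' @param z compounds x genes matrix of differential-expression z-scores;
#'   finite entries, unique compound rownames, gene colnames.
#' @param annotations data.frame with columns `compound` and
#'   `lifespan_reported` (logical), one row per compound.
#' @return A `drug_profile_matrix` object.
#' @export
drug_profile_matrix <- function(z, annotations) {
  stopifnot(is.matrix(z), !is.null(rownames(z)), !is.null(colnames(z)),
            all(is.finite(z)),
            all(c("compound", "lifespan_reported") %in% names(annotations)))
  if (anyDuplicated(rownames(z))) stop("compound names must be unique")
  if (!setequal(annotations$compound, rownames(z))) {
    stop("annotations and z-matrix disagree on compounds")
  }
  annotations <- annotations[match(rownames(z), annotations$compound), ,
                             drop = FALSE]
  rownames(annotations) <- NULL
  structure(list(z = z, annotations = annotations),
            class = "drug_profile_matrix")
}

#' @export
print.drug_profile_matrix <- function(x, ...) {
  cat(sprintf("drug_profile_matrix: %d compounds x %d genes (%d lifespan-flagged)\n",
              nrow(x$z), ncol(x$z), sum(x$annotations$lifespan_reported)))
  invisible(x)
}

#' Matrisome regulation score of a single drug profile
#'
#' Standardizes the mean z-score over the matrisome genes against an
#' empirical null of size-matched random gene sets drawn from the same
#' profile: `score = (mean(z[M]) - mean_null) / sd_null`. This controls for
#' drug-wide expression shifts. When the number of possible subsets
#' `choose(|U|, |M|)` is at most `exhaustive_limit` the null is enumerated
#' exactly; otherwise the null mean is estimated from `n_null` uniform
#' draws (one seeded stream). In both modes `sd_null` is the exact standard
#' deviation of a size-`|M|` subset mean under sampling without replacement
#' (`sqrt(S^2 / m * (1 - m/N))`, `S^2` the profile variance): estimating
#' the sd from draws would add noise proportional to the score itself.
#' A degenerate null (`sd_null < 1e-12`, e.g. an all-constant profile)
#' yields score 0 with `degenerate = TRUE`.
#'
#' @param profile named numeric vector of z-scores over the gene universe.
#' @param matrisome character vector of matrisome genes (>= 2 after
#'   intersection with the universe).
#' @param n_null number of null gene sets when sampling (default 1000).
#' @param seed integer seed for the null draws.
#' @param mode `"auto"` (exhaustive when feasible), `"sampled"` or
#'   `"exhaustive"`.
#' @param exhaustive_limit subset-count ceiling for automatic enumeration.
#' @return List with `score`, `mean_set`, `null_mean`, `null_sd`,
#'   `degenerate`, `mode`.
#' @export
matrisome_regulation_score <- function(profile, matrisome, n_null = 1000,
                                       seed = 1L,
                                       mode = c("auto", "sampled",
                                                "exhaustive"),
                                       exhaustive_limit = 1e5) {
  mode <- match.arg(mode)
  stopifnot(!is.null(names(profile)))
  m_genes <- intersect(matrisome, names(profile))
  if (!length(matrisome)) stop("matrisome set is empty")
  if (length(m_genes) < 2) stop("need >= 2 matrisome genes in the universe")
  z <- as.numeric(profile)
  n <- length(z)
  m <- length(m_genes)
  s <- mean(profile[m_genes])
  n_subsets <- choose(n, m)
  use_exhaustive <- mode == "exhaustive" ||
    (mode == "auto" && n_subsets <= exhaustive_limit)
  if (use_exhaustive && n_subsets > exhaustive_limit) {
    stop("exhaustive null infeasible: choose(", n, ", ", m, ") subsets")
  }
  if (use_exhaustive) {
    means <- colMeans(matrix(z[utils::combn(n, m)], nrow = m))
    mu <- mean(means)
    # population sd: the enumeration IS the exact null distribution
    sdv <- sqrt(mean((means - mu)^2))
  } else {
    means <- with_rng(seed, {
      vapply(seq_len(n_null),
             function(i) mean(z[sample.int(n, m)]), numeric(1))
    })
    mu <- mean(means)
    sdv <- sqrt(stats::var(z) / m * (1 - m / n))
  }
  degenerate <- !is.finite(sdv) || sdv < 1e-12
  list(score = if (degenerate) 0 else (s - mu) / sdv,
       mean_set = s, null_mean = mu, null_sd = sdv,
       degenerate = degenerate,
       mode = if (use_exhaustive) "exhaustive" else "sampled")
}

#' Matrisome regulation scores for a whole drug library
#'
#' Vectorised form of [matrisome_regulation_score()] for all compounds of a
#' `drug_profile_matrix`. For speed the `n_null` random size-matched gene
#' sets are drawn once and evaluated against every profile (each drug's
#' null mean and exact null sd are still built from its own z values, as in
#' the single-profile form).
#'
#' @param profiles a `drug_profile_matrix`.
#' @param matrisome character vector of matrisome genes.
#' @param n_null,seed as in [matrisome_regulation_score()].
#' @return data.frame with columns compound, score, degenerate.
#' @export
regulation_scores <- function(profiles, matrisome, n_null = 1000,
                              seed = 1L) {
  stopifnot(inherits(profiles, "drug_profile_matrix"))
  z <- profiles$z
  m_genes <- intersect(matrisome, colnames(z))
  if (length(m_genes) < 2) stop("need >= 2 matrisome genes in the universe")
  n <- ncol(z)
  m <- length(m_genes)
  s <- rowMeans(z[, m_genes, drop = FALSE])
  draws <- with_rng(seed, {
    vapply(seq_len(n_null), function(i) sample.int(n, m), integer(m))
  })
  # indicator matrix (genes x n_null) of subset membership, scaled to means
  ind <- matrix(0, nrow = n, ncol = n_null)
  ind[cbind(as.vector(draws), rep(seq_len(n_null), each = m))] <- 1 / m
  null_means <- z %*% ind                      # compounds x n_null
  mu <- rowMeans(null_means)
  row_var <- apply(z, 1L, stats::var)
  sdv <- sqrt(row_var / m * (1 - m / n))
  degenerate <- !is.finite(sdv) | sdv < 1e-12
  score <- ifelse(degenerate, 0, (s - mu) / sdv)
  data.frame(compound = rownames(z), score = unname(score),
             degenerate = unname(degenerate), stringsAsFactors = FALSE)
}

#' Classify compounds by matrisome regulation score
#'
#' Partition at the standardized threshold (default 1.5): `increased` for
#' `score >= threshold`, `decreased` for `score <= -threshold`, `minor`
#' otherwise. The partition is exhaustive and disjoint.
#'
#' @param scores data.frame with columns `compound` and `score` (as from
#'   [regulation_scores()]), or a named numeric vector.
#' @param threshold positive classification threshold.
#' @return data.frame compound/score/classification.
#' @export
classify_matrisome_response <- function(scores, threshold = 1.5) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (is.numeric(scores)) {
    scores <- data.frame(compound = names(scores), score = unname(scores),
                         stringsAsFactors = FALSE)
  }
  cls <- ifelse(scores$score >= threshold, "increased",
                ifelse(scores$score <= -threshold, "decreased", "minor"))
  data.frame(compound = scores$compound, score = scores$score,
             classification = cls, stringsAsFactors = FALSE)
}

#' Concordance of drug profiles with one directional signature half
#'
#' For each compound, `m` is the mean z over the half's genes present in the
#' measured universe. For the `up_with_age` half a *reversing* drug pushes
#' those genes down, so the reversed score is `-m` and the potentiated score
#' `+m`; for the `down_with_age` half the signs flip. Ranks are assigned per
#' mode by descending score with alphabetical tie-break.
#'
#' @param profiles a `drug_profile_matrix`.
#' @param half_genes genes of the signature half.
#' @param half `"up_with_age"` or `"down_with_age"`.
#' @return data.frame compound/half/mode/score/rank (both modes stacked).
#' @export
concordance_scores <- function(profiles, half_genes,
                               half = c("up_with_age", "down_with_age")) {
  half <- match.arg(half)
  stopifnot(inherits(profiles, "drug_profile_matrix"))
  measured <- intersect(half_genes, colnames(profiles$z))
  if (!length(measured)) {
    stop("no signature gene measured; missing: ",
         paste(half_genes, collapse = ", "))
  }
  n_missing <- length(half_genes) - length(measured)
  if (n_missing > 0) {
    message(n_missing, " signature gene(s) not measured; dropped")
  }
  m <- rowMeans(profiles$z[, measured, drop = FALSE])
  reversed <- if (half == "up_with_age") -m else m
  out <- lapply(c(reversed = 1, potentiated = -1), function(sgn) {
    score <- sgn * reversed
    ord <- order(-score, rownames(profiles$z))
    rank <- integer(length(score))
    rank[ord] <- seq_along(score)
    data.frame(compound = rownames(profiles$z), half = half,
               score = unname(score), rank = rank,
               stringsAsFactors = FALSE)
  })
  out$reversed$mode <- "reversed"
  out$potentiated$mode <- "potentiated"
  res <- rbind(out$reversed, out$potentiated)
  res[, c("compound", "half", "mode", "score", "rank")]
}

#' Whole-signature concordance scores
#'
#' Signed mean of z over all signature genes: each gene contributes with
#' weight `-1` if `up_with_age` and `+1` if `down_with_age`, so a positive
#' reversed score means the drug moves the signature toward youth. The
#' potentiated score is the exact negation, and the reversed score on a
#' signature equals the potentiated score on its inversion.
#'
#' @param profiles a `drug_profile_matrix`.
#' @param sig a `matreotype_signature`.
#' @return data.frame compound/reversed/potentiated.
#' @export
signature_concordance <- function(profiles, sig) {
  stopifnot(inherits(profiles, "drug_profile_matrix"),
            inherits(sig, "matreotype_signature"))
  entries <- sig$entries[sig$entries$gene %in% colnames(profiles$z), ,
                         drop = FALSE]
  if (!nrow(entries)) stop("no signature gene measured")
  sgn <- ifelse(entries$direction == "up_with_age", -1, 1)
  reversed <- as.vector(profiles$z[, entries$gene, drop = FALSE] %*% sgn) /
    nrow(entries)
  data.frame(compound = rownames(profiles$z), reversed = reversed,
             potentiated = -reversed, stringsAsFactors = FALSE)
}

#' Top-k compounds by score
#'
#' Deterministic ranking: descending score, ties broken by ascending
#' compound name; returns all rows when fewer than `k` are available. The
#' output is prefix-stable in `k`.
#'
#' @param results data.frame with columns `compound` and `score`.
#' @param k list length (>= 1).
#' @return The top-`k` rows with a `rank` column.
#' @export
top_k <- function(results, k = 50) {
  if (k < 1) stop("k must be >= 1")
  ord <- order(-results$score, results$compound)
  out <- results[utils::head(ord, k), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Compile the four directional hit lists into one compendium
#'
#' Takes the 2 x 2 design of top-k lists (signature half x concordance mode)
#' and reports the unique compound set plus the number of compounds selected
#' by both the youthful-concordant (reversed) and aged-concordant
#' (potentiated) sides.
#'
#' @param lists named list of four character vectors (or data.frames with a
#'   `compound` column); names must contain `"reversed"` or `"potentiated"`.
#' @return List with `lists`, `unique` (sorted union), `n_unique`,
#'   `overlap_count` and `n_total_entries`.
#' @export
compile_hit_sets <- function(lists) {
  lists <- lapply(lists, function(x) {
    if (is.data.frame(x)) x$compound else as.character(x)
  })
  is_rev <- grepl("reversed", names(lists))
  is_pot <- grepl("potentiated", names(lists))
  if (!any(is_rev) || !any(is_pot) || any(!(is_rev | is_pot))) {
    stop("lists must be named by mode (reversed / potentiated)")
  }
  all_names <- unlist(lists, use.names = FALSE)
  uni <- sort(unique(all_names))
  overlap <- intersect(unique(unlist(lists[is_rev], use.names = FALSE)),
                       unique(unlist(lists[is_pot], use.names = FALSE)))
  list(lists = lists, unique = uni, n_unique = length(uni),
       overlap_count = length(overlap), n_total_entries = length(all_names))
}

#' Lifespan-flag enrichment of a hit list
#'
#' Percentages are reported at full precision with integer-rounded display
#' values; the p-value is the upper tail of the hypergeometric distribution
#' (probability of drawing at least `n_hit_flagged` flagged compounds in
#' `n_hits` draws from a library of `n_bg` containing `n_bg_flagged`
#' flagged ones).
#'
#' @param n_hit_flagged flagged compounds among the hits.
#' @param n_hits number of hit compounds.
#' @param n_bg_flagged flagged compounds in the whole library.
#' @param n_bg library size.
#' @return List with `pct_hit`, `pct_bg`, `pct_hit_display`,
#'   `pct_bg_display`, `fold`, `p_hypergeometric`.
#' @export
enrichment_stats <- function(n_hit_flagged, n_hits, n_bg_flagged, n_bg) {
  if (n_hits <= 0 || n_bg <= 0) stop("zero denominator")
  if (n_hit_flagged > n_hits || n_hits > n_bg ||
      n_hit_flagged > n_bg_flagged || n_bg_flagged > n_bg) {
    stop("inconsistent counts")
  }
  pct_hit <- 100 * n_hit_flagged / n_hits
  pct_bg <- 100 * n_bg_flagged / n_bg
  list(pct_hit = pct_hit, pct_bg = pct_bg,
       pct_hit_display = round(pct_hit), pct_bg_display = round(pct_bg),
       fold = if (pct_bg > 0) pct_hit / pct_bg else NA_real_,
       p_hypergeometric = stats::phyper(n_hit_flagged - 1, n_bg_flagged,
                                        n_bg - n_bg_flagged, n_hits,
                                        lower.tail = FALSE))
}

#' Hierarchical clustering orders for heatmap display
#'
#' Agglomerative clustering with average linkage on correlation distance
#' (`1 - Pearson r`) over rows and columns. Zero-variance rows or columns
#' have undefined correlation; their distances are set to the maximum (2)
#' and the offenders are flagged.
#'
#' @param m numeric matrix, at least 2 x 2.
#' @return List with `row_order`, `col_order`, `row_hclust`, `col_hclust`,
#'   `flagged_rows`, `flagged_cols`, `linkage`, `distance`.
#' @export
cluster_for_display <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2, ncol(m) >= 2)
  one_axis <- function(x) {
    v <- apply(x, 1L, stats::var)
    flagged <- which(v == 0 | !is.finite(v))
    cm <- suppressWarnings(stats::cor(t(x)))
    d <- 1 - cm
    d[!is.finite(d)] <- 2
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    list(hclust = hc, order = hc$order, flagged = flagged)
  }
  rows <- one_axis(m)
  cols <- one_axis(t(m))
  list(row_order = rows$order, col_order = cols$order,
       row_hclust = rows$hclust, col_hclust = cols$hclust,
       flagged_rows = rows$flagged, flagged_cols = cols$flagged,
       linkage = "average", distance = "1 - Pearson correlation")
}
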