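# Evaluate expr under a private RNG stream, restoring the caller's state.
# All generators are pure functions of (config, seed).
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Configuration for the age-stratified cohort simulator
#'
#' The generator emulates age-stratified human tissue transcriptomes: a
#' subset of matrisome genes is planted with a monotone age trend on the log
#' scale (collagen-like genes falling, protease-like genes rising), while
#' all other genes are age-flat. Defaults describe a desk-scale cohort:
#' six decade brackets (20s-70s), 30 donors per bracket, residual log-scale
#' standard deviation 0.5 and a planted end-to-end log shift of 1.0
#' (i.e. twice the noise SD).
#'
#' @param n_genes total genes per tissue.
#' @param n_matrisome number of matrisome genes (must not exceed `n_genes`).
#' @param tissues tissue labels; defaults to the five vessel/gland/skin
#'   tissues with usable age signal.
#' @param donors_per_bracket donors per age bracket per tissue.
#' @param age_brackets named numeric vector: bracket label -> midpoint (years).
#' @param effect_size log-scale shift between the youngest and oldest bracket
#'   midpoint for planted genes (>= 0).
#' @param frac_planted_up,frac_planted_down fractions of matrisome genes
#'   planted up / down with age; must sum to at most 1.
#' @param noise_sd residual log-scale SD (> 0).
#' @param seed integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_genes = 200, n_matrisome = 40,
                          tissues = c("skin", "thyroid", "pituitary",
                                      "aorta", "coronary_artery"),
                          donors_per_bracket = 30,
                          age_brackets = c("20s" = 25, "30s" = 35, "40s" = 45,
                                           "50s" = 55, "60s" = 65, "70s" = 75),
                          effect_size = 1.0,
                          frac_planted_up = 0.25, frac_planted_down = 0.25,
                          noise_sd = 0.5, seed = 1L) {
  if (n_matrisome > n_genes) stop("n_matrisome exceeds n_genes")
  if (frac_planted_up + frac_planted_down > 1) {
    stop("frac_planted_up + frac_planted_down must be <= 1")
  }
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (length(age_brackets) < 2) stop("need at least 2 age brackets")
  structure(list(n_genes = n_genes, n_matrisome = n_matrisome,
                 tissues = tissues,
                 donors_per_bracket = donors_per_bracket,
                 age_brackets = age_brackets, effect_size = effect_size,
                 frac_planted_up = frac_planted_up,
                 frac_planted_down = frac_planted_down,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate age-stratified expression cohorts with planted matrisome aging
#'
#' Expression is simulated on the log scale as
#' `baseline + slope * (midpoint - youngest midpoint) + N(0, noise_sd)` and
#' exponentiated for output, so baselines are positive and relative change is
#' well-defined. The planted slope is linear in the bracket midpoint and
#' scaled so that the full young-to-old shift equals `effect_size`. The same
#' planted genes (and directions) are used in every tissue, so a multi-source
#' consensus can recover them.
#'
#' @param cfg a [cohort_config()].
#' @return List with `cohorts` (named list of `expression_cohort`, one per
#'   tissue), `truth` (data.frame gene/tissue/direction for planted genes)
#'   and `collection` (a `gene_set_collection` whose matrisome holds the
#'   first `n_matrisome` genes, split over the six categories).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  labels <- matrisome_category_labels()
  mat_genes <- sprintf("MAT%03d", seq_len(cfg$n_matrisome))
  bg_genes <- if (cfg$n_genes > cfg$n_matrisome) {
    sprintf("BG%03d", seq_len(cfg$n_genes - cfg$n_matrisome))
  } else character(0)
  genes <- c(mat_genes, bg_genes)
  cat_of <- rep_len(labels, cfg$n_matrisome)
  coll <- gene_set_collection(
    split(mat_genes, factor(cat_of, levels = labels)),
    categories = stats::setNames(cat_of, mat_genes))

  n_up <- round(cfg$frac_planted_up * cfg$n_matrisome)
  n_dn <- round(cfg$frac_planted_down * cfg$n_matrisome)
  planted_up <- mat_genes[seq_len(n_up)]
  planted_dn <- mat_genes[n_up + seq_len(n_dn)]
  mids <- cfg$age_brackets
  span <- max(mids) - min(mids)
  slope <- numeric(cfg$n_genes)
  names(slope) <- genes
  slope[planted_up] <- cfg$effect_size / span
  slope[planted_dn] <- -cfg$effect_size / span

  cohorts <- with_rng(cfg$seed, {
    baseline <- stats::rnorm(cfg$n_genes, mean = 5, sd = 1)
    names(baseline) <- genes
    out <- lapply(cfg$tissues, function(tissue) {
      bracket <- rep(names(mids), each = cfg$donors_per_bracket)
      midpoint <- mids[bracket]
      donors <- sprintf("%s_d%03d", tissue, seq_along(bracket))
      logx <- outer(baseline, rep(1, length(donors))) +
        outer(slope, midpoint - min(mids)) +
        matrix(stats::rnorm(cfg$n_genes * length(donors),
                            sd = cfg$noise_sd),
               nrow = cfg$n_genes)
      dimnames(logx) <- list(genes, donors)
      expression_cohort(exp(logx), tissue = tissue,
                        brackets = data.frame(donor = donors,
                                              bracket = bracket,
                                              midpoint = unname(midpoint)))
    })
    stats::setNames(out, cfg$tissues)
  })

  truth <- expand.grid(gene = c(planted_up, planted_dn),
                       tissue = cfg$tissues, stringsAsFactors = FALSE)
  truth$direction <- ifelse(truth$gene %in% planted_up,
                            "up_with_age", "down_with_age")
  list(cohorts = cohorts, truth = truth, collection = coll)
}

#' Age-stratified expression cohort container
#'
#' @param matrix genes x donors non-negative expression matrix with dimnames.
#' @param tissue tissue label.
#' @param brackets data.frame with columns `donor`, `bracket`, `midpoint`;
#'   one row per donor column of `matrix`.
#' @return An `expression_cohort` object.
#' @export
expression_cohort <- function(matrix, tissue, brackets) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            all(c("donor", "bracket", "midpoint") %in% names(brackets)))
  if (!identical(colnames(matrix), brackets$donor)) {
    stop("donor columns and bracket table disagree")
  }
  if (any(matrix < 0)) stop("expression values must be non-negative")
  if (length(unique(brackets$bracket)) < 2) {
    stop("need at least 2 age brackets")
  }
  structure(list(matrix = matrix, tissue = tissue, brackets = brackets),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("expression_cohort [%s]: %d genes x %d donors, brackets: %s\n",
              x$tissue, nrow(x$matrix), ncol(x$matrix),
              paste(unique(x$brackets$bracket), collapse = " ")))
  invisible(x)
}

#' Configuration for the drug perturbation-library simulator
#'
#' Background drug-by-gene z-scores are i.i.d. standard normal. Planted
#' "reversed" drugs shift signature genes against their aging direction by
#' `delta` (planted "potentiated" drugs shift with it). Lifespan flags are
#' independent Bernoulli draws whose rate depends on planted status; the
#' defaults (5% background, 25% planted) reproduce a hit-list lifespan
#' enrichment in the low-teens of percent against a 5% background, the
#' pattern seen in the published screen.
#'
#' @param n_drugs number of compounds.
#' @param n_genes measured-gene universe size (signature genes are always
#'   included; the remainder are filler genes).
#' @param n_planted_reversed,n_planted_potentiated planted drug counts.
#' @param delta planted per-gene z offset on signature genes.
#' @param lifespan_base_rate,lifespan_planted_rate Bernoulli flag rates in
#'   `[0, 1]` for non-planted / planted drugs.
#' @param seed integer seed.
#' @return A `drug_library_config` list.
#' @export
drug_library_config <- function(n_drugs = 500, n_genes = 200,
                                n_planted_reversed = 20,
                                n_planted_potentiated = 20,
                                delta = 1.0,
                                lifespan_base_rate = 0.05,
                                lifespan_planted_rate = 0.25,
                                seed = 1L) {
  rates <- c(lifespan_base_rate, lifespan_planted_rate)
  if (any(rates < 0 | rates > 1)) stop("lifespan rates must be in [0, 1]")
  if (n_planted_reversed + n_planted_potentiated > n_drugs) {
    stop("more planted drugs than drugs")
  }
  structure(list(n_drugs = n_drugs, n_genes = n_genes,
                 n_planted_reversed = n_planted_reversed,
                 n_planted_potentiated = n_planted_potentiated,
                 delta = delta,
                 lifespan_base_rate = lifespan_base_rate,
                 lifespan_planted_rate = lifespan_planted_rate,
                 seed = as.integer(seed)),
            class = "drug_library_config")
}

#' Simulate a drug-by-gene differential-expression z-score library
#'
#' @param cfg a [drug_library_config()].
#' @param signature a `matreotype_signature` of kind `"aged"`; planted
#'   reversed drugs move its genes against their aging direction.
#' @return List with `profiles` (a `drug_profile_matrix`) and `truth`
#'   (data.frame compound/planted/lifespan_reported with planted in
#'   none/reversed/potentiated).
#' @export
simulate_drug_library <- function(cfg, signature) {
  stopifnot(inherits(cfg, "drug_library_config"),
            inherits(signature, "matreotype_signature"))
  if (!nrow(signature$entries)) stop("signature must be non-empty")
  sig <- signature$entries
  if (cfg$n_genes < nrow(sig)) stop("n_genes smaller than the signature")
  filler <- sprintf("FILL%03d", seq_len(cfg$n_genes - nrow(sig)))
  genes <- c(sig$gene, filler)
  drugs <- sprintf("drug%04d", seq_len(cfg$n_drugs))
  up <- sig$gene[sig$direction == "up_with_age"]
  dn <- sig$gene[sig$direction == "down_with_age"]

  with_rng(cfg$seed, {
    z <- matrix(stats::rnorm(cfg$n_drugs * cfg$n_genes),
                nrow = cfg$n_drugs, dimnames = list(drugs, genes))
    planted_idx <- sample.int(cfg$n_drugs,
                              cfg$n_planted_reversed + cfg$n_planted_potentiated)
    rev_idx <- planted_idx[seq_len(cfg$n_planted_reversed)]
    pot_idx <- setdiff(planted_idx, rev_idx)
    z[rev_idx, up] <- z[rev_idx, up] - cfg$delta
    z[rev_idx, dn] <- z[rev_idx, dn] + cfg$delta
    z[pot_idx, up] <- z[pot_idx, up] + cfg$delta
    z[pot_idx, dn] <- z[pot_idx, dn] - cfg$delta
    planted <- rep("none", cfg$n_drugs)
    planted[rev_idx] <- "reversed"
    planted[pot_idx] <- "potentiated"
    rate <- ifelse(planted == "none", cfg$lifespan_base_rate,
                   cfg$lifespan_planted_rate)
    flags <- stats::runif(cfg$n_drugs) < rate
    ann <- data.frame(compound = drugs, lifespan_reported = flags,
                      notes = "", stringsAsFactors = FALSE)
    list(profiles = drug_profile_matrix(z, ann),
         truth = data.frame(compound = drugs, planted = planted,
                            lifespan_reported = flags,
                            stringsAsFactors = FALSE))
  })
}

#' ECM literature keywords
#'
#' The ten matrisome keywords used to flag abstracts of longevity studies as
#' ECM-linked, in canonical order.
#'
#' @return Character vector of length 10.
#' @export
ecm_keywords <- function() {
  c("collagen", "ECM", "extracellular", "matrix", "proteoglycan",
    "hyaluronic", "hyaluronan", "TGF", "integrin", "TGFbeta")
}

#' Simulate abstracts with a planted number of distinct ECM keywords
#'
#' Each abstract embeds exactly the first `k` keywords of [ecm_keywords()]
#' (taken in canonical order, which guarantees the distinct-prefix-match
#' count equals `k`) in keyword-free filler text.
#'
#' @param compounds character vector of compound names.
#' @param planted_keyword_counts named integer vector (compound -> count in
#'   `0..10`), or a single count recycled to all compounds.
#' @return data.frame with columns `compound`, `planted_keywords`,
#'   `abstract_text`.
#' @export
simulate_abstracts <- function(compounds, planted_keyword_counts) {
  if (length(planted_keyword_counts) == 1 &&
      is.null(names(planted_keyword_counts))) {
    planted_keyword_counts <- stats::setNames(
      rep(planted_keyword_counts, length(compounds)), compounds)
  }
  unknown <- setdiff(names(planted_keyword_counts), compounds)
  if (length(unknown)) {
    stop("unknown compound in planted_keyword_counts: ",
         paste(unknown, collapse = ", "))
  }
  counts <- stats::setNames(rep(0L, length(compounds)), compounds)
  counts[names(planted_keyword_counts)] <- planted_keyword_counts
  if (any(counts < 0) || any(counts > length(ecm_keywords()))) {
    stop("planted counts must be in 0..", length(ecm_keywords()))
  }
  filler <- paste("Treatment of nematodes with the agent produced a",
                  "reproducible change in median survival relative to",
                  "vehicle controls across independent trials.")
  text <- vapply(compounds, function(cmp) {
    k <- counts[[cmp]]
    planted <- if (k > 0) {
      paste("The study also reports effects on",
            paste(ecm_keywords()[seq_len(k)], collapse = " and "),
            "related biology.")
    } else ""
    trimws(paste(cmp, "was assayed for longevity.", filler, planted))
  }, character(1))
  data.frame(compound = compounds, planted_keywords = unname(counts),
             abstract_text = unname(text), stringsAsFactors = FALSE)
}

#' Configuration for the collagen-reporter assay simulator
#'
#' Emulates the near-linear decline of a collagen promoter-driven GFP
#' reporter over adulthood days 1-5, with a Gaussian (single-optimum,
#' U/J-compatible) dose effect that slows the decline. Mean intensity is
#' `max(0, intercept - slope * day + drug_effect_max *
#' exp(-(dose - optimum_dose)^2 / (2 * dose_width^2)) * day / max(days))`,
#' plus Gaussian noise; a `"control"` arm at dose 0 has zero drug effect.
#'
#' @param n_animals animals per arm.
#' @param days observation days of adulthood.
#' @param intercept,slope intercept and decline rate of the control mean
#'   (intensity units, units/day); `slope > 0` means decline.
#' @param drug_effect_max maximal slowing of decline (intensity units at the
#'   final day).
#' @param optimum_dose,dose_width Gaussian dose-response optimum and width.
#' @param doses tested doses (non-negative; dose 0 is reserved for control).
#' @param dose_unit unit string carried through, never converted.
#' @param noise_sd residual intensity SD.
#' @param seed integer seed.
#' @return A `reporter_config` list.
#' @export
reporter_config <- function(n_animals = 50, days = 1:5,
                            intercept = 6, slope = 1,
                            drug_effect_max = 0.5,
                            optimum_dose = 10, dose_width = 5,
                            doses = c(1, 5, 10, 50, 100),
                            dose_unit = "uM",
                            noise_sd = 0.2, seed = 1L) {
  if (slope <= 0) stop("slope must be > 0 (declining reporter)")
  if (any(doses < 0)) stop("doses must be non-negative")
  structure(list(n_animals = n_animals, days = days, intercept = intercept,
                 slope = slope, drug_effect_max = drug_effect_max,
                 optimum_dose = optimum_dose, dose_width = dose_width,
                 doses = doses, dose_unit = dose_unit, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "reporter_config")
}

#' Simulate reporter-intensity trajectories under a dose series
#'
#' @param cfg a [reporter_config()].
#' @return List with `trajectories` (tidy data.frame animal_id/day/drug/dose/
#'   dose_unit/intensity) and `truth` (data.frame dose/drug_effect, i.e. the
#'   planted mean effect at the final day, plus the optimum dose as an
#'   attribute-free column `is_optimum`).
#' @export
simulate_reporter <- function(cfg) {
  stopifnot(inherits(cfg, "reporter_config"))
  arms <- data.frame(drug = c("control", rep("drug", length(cfg$doses))),
                     dose = c(0, cfg$doses), stringsAsFactors = FALSE)
  day_factor <- function(day) day / max(cfg$days)
  dose_gain <- function(dose) {
    exp(-(dose - cfg$optimum_dose)^2 / (2 * cfg$dose_width^2))
  }
  rows <- with_rng(cfg$seed, {
    out <- lapply(seq_len(nrow(arms)), function(i) {
      arm <- arms[i, ]
      effect <- if (arm$drug == "control") 0 else {
        cfg$drug_effect_max * dose_gain(arm$dose)
      }
      grid <- expand.grid(animal = seq_len(cfg$n_animals), day = cfg$days)
      mu <- pmax(0, cfg$intercept - cfg$slope * grid$day +
                   effect * day_factor(grid$day))
      data.frame(
        animal_id = sprintf("%s_%g_a%03d", arm$drug, arm$dose, grid$animal),
        day = grid$day, drug = arm$drug, dose = arm$dose,
        dose_unit = cfg$dose_unit,
        intensity = pmax(0, mu + stats::rnorm(nrow(grid),
                                              sd = cfg$noise_sd)),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  truth <- data.frame(dose = cfg$doses,
                      drug_effect = cfg$drug_effect_max *
                        dose_gain(cfg$doses))
  truth$is_optimum <- truth$drug_effect == max(truth$drug_effect)
  list(trajectories = rows, truth = truth)
}
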