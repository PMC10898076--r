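# ECM adhesion-array profiling: the 36-composition panel, a Poisson spot
# simulator, replicate aggregation, reference normalisation,
# Pearson-correlation similarity and per-composition Welch tests.

#' The nine ECM proteins of the adhesion panel
#' @return character vector of protein names.
#' @export
ecm_proteins <- function() {
  c("Collagen I", "Collagen III", "Collagen IV", "Collagen V", "Collagen VI",
    "Laminin", "Fibronectin", "Vitronectin", "Tropoelastin")
}

# Curated mixes completing the default panel: the nine singletons plus 27
# pairwise/triple combinations (19 pairs, 8 triples). The named mixes with
# reported condition-specific adhesion differences are all present.
.ecm_mixes <- list(
  c("Collagen I", "Collagen III"),
  c("Collagen I", "Collagen IV"),
  c("Collagen I", "Collagen V"),
  c("Collagen I", "Collagen VI"),
  c("Collagen I", "Laminin"),
  c("Collagen I", "Fibronectin"),
  c("Collagen I", "Vitronectin"),
  c("Collagen I", "Tropoelastin"),
  c("Laminin", "Collagen III"),
  c("Laminin", "Collagen IV"),
  c("Laminin", "Collagen V"),
  c("Laminin", "Collagen VI"),
  c("Laminin", "Fibronectin"),
  c("Laminin", "Vitronectin"),
  c("Laminin", "Tropoelastin"),
  c("Fibronectin", "Collagen IV"),
  c("Fibronectin", "Vitronectin"),
  c("Fibronectin", "Tropoelastin"),
  c("Vitronectin", "Tropoelastin"),
  c("Fibronectin", "Laminin", "Collagen I"),
  c("Collagen I", "Collagen III", "Collagen V"),
  c("Collagen IV", "Collagen VI", "Laminin"),
  c("Collagen I", "Fibronectin", "Vitronectin"),
  c("Laminin", "Fibronectin", "Tropoelastin"),
  c("Collagen III", "Collagen IV", "Collagen VI"),
  c("Collagen I", "Laminin", "Tropoelastin"),
  c("Collagen V", "Laminin", "Fibronectin")
)

#' Default 36-composition ECM panel
#'
#' The nine single proteins plus 27 curated pairwise and triple mixes, 36
#' distinct compositions in total. Each label joins its components with
#' `" + "`; every component is one of [ecm_proteins()].
#'
#' @return character vector of 36 composition labels.
#' @examples
#' length(ecm_panel_default())  # 36
#' @export
ecm_panel_default <- function() {
  c(ecm_proteins(),
    vapply(.ecm_mixes, paste, character(1), collapse = " + "))
}

#' Split composition labels into their protein components
#' @param labels composition labels (`" + "`-joined protein names).
#' @return list of character vectors.
#' @export
ecm_panel_components <- function(labels) {
  strsplit(labels, " + ", fixed = TRUE)
}

#' Simulate an ECM adhesion array
#'
#' Draws Poisson-distributed attached-cell counts per (condition,
#' composition, replicate) around the supplied mean-count (propensity)
#' table, emulating nucleus counts on printed ECM spots.
#'
#' @param propensity numeric matrix of non-negative mean counts, conditions
#'   in rows (rownames required), compositions in columns; unnamed columns
#'   take the default 36-composition panel.
#' @param n_replicates replicate spots per (condition, composition).
#' @param seed integer seed.
#' @return an `adhesion_matrix`: long-format data frame `condition`,
#'   `composition`, `replicate`, `count`.
#' @export
simulate_ecm_array <- function(propensity, n_replicates = 3L, seed = NULL) {
  if (!is.matrix(propensity) || !is.numeric(propensity))
    stop_param("'propensity' must be a numeric condition x composition matrix")
  if (any(propensity < 0)) stop_param("propensities must be >= 0")
  if (is.null(rownames(propensity)))
    stop_param("'propensity' needs condition rownames")
  if (is.null(colnames(propensity))) {
    if (ncol(propensity) != 36L)
      stop_param("unnamed propensity columns must match the 36-composition default panel")
    colnames(propensity) <- ecm_panel_default()
  }
  n_replicates <- check_count(n_replicates, "n_replicates")

  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        composition = colnames(propensity),
                        condition = rownames(propensity),
                        stringsAsFactors = FALSE)
    mu <- propensity[cbind(grid$condition, grid$composition)]
    out <- data.frame(condition = grid$condition,
                      composition = grid$composition,
                      replicate = grid$replicate,
                      count = stats::rpois(nrow(grid), mu))
    class(out) <- c("adhesion_matrix", "data.frame")
    out
  })
}

check_adhesion <- function(x) {
  need <- c("condition", "composition", "replicate", "count")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop_param("adhesion data needs columns: ", paste(need, collapse = ", "))
  if (any(x$count < 0) || any(x$count != floor(x$count)))
    stop_param("counts must be non-negative integers")
  comp_sets <- tapply(x$composition, x$condition, function(v) sort(unique(v)))
  if (length(unique(vapply(comp_sets, paste, character(1), collapse = "|"))) != 1L)
    stop_param("every condition must cover the same composition set")
  invisible(x)
}

#' Replicate-mean adhesion profiles
#'
#' @param x an `adhesion_matrix` (long-format counts).
#' @return condition x composition matrix of replicate means, with the
#'   replicate counts in attribute `n_replicates`.
#' @export
profile_means <- function(x) {
  check_adhesion(x)
  # keep conditions and compositions in first-appearance order
  idx <- list(factor(x$condition, levels = unique(x$condition)),
              factor(x$composition, levels = unique(x$composition)))
  m <- tapply(x$count, idx, mean)
  n <- tapply(x$count, idx, length)
  if (anyNA(n) || any(n == 0))
    stop_param("a condition has zero replicates for some composition")
  attr(m, "n_replicates") <- n
  m
}

#' Normalise adhesion profiles to a reference condition
#'
#' Per-composition ratio of each condition's mean count to the reference
#' condition's mean count. Compositions with a zero reference mean are
#' flagged NA rather than divided.
#'
#' @param means condition x composition mean matrix from [profile_means()].
#' @param reference reference condition (rowname), e.g. the wild type.
#' @return condition x composition matrix of normalised effects.
#' @export
normalize_to_reference <- function(means, reference) {
  if (!reference %in% rownames(means))
    stop_param("reference condition '", reference, "' not found")
  ref <- means[reference, ]
  zero <- ref == 0
  if (any(zero))
    warning(sum(zero), " composition(s) with zero reference mean flagged NA",
            call. = FALSE)
  out <- sweep(means, 2L, ifelse(zero, NA_real_, ref), `/`)
  out
}

#' Pearson-correlation similarity of adhesion profiles
#'
#' Pearson correlation between each pair of condition profiles across the
#' composition panel, the derived correlation distance `1 - r`, and the
#' scaled distance (distance divided by the largest off-diagonal distance
#' among the compared conditions, so the most dissimilar pair scores 1).
#' A condition with zero profile variance has undefined correlations and is
#' flagged NA.
#'
#' @param means condition x composition mean matrix.
#' @return a `similarity_result` list: `pearson_r`, `distance`,
#'   `scaled_distance` (condition x condition matrices).
#' @export
pearson_similarity <- function(means) {
  if (ncol(means) < 2L)
    stop_param("need at least 2 compositions")
  sds <- apply(means, 1L, stats::sd)
  if (any(sds == 0))
    warning("zero-variance profile(s): ",
            paste(rownames(means)[sds == 0], collapse = ", "),
            "; correlations flagged NA", call. = FALSE)
  r <- suppressWarnings(stats::cor(t(means)))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  d <- 1 - r
  off <- d[upper.tri(d) | lower.tri(d)]
  dmax <- if (all(is.na(off))) NA_real_ else max(off, na.rm = TRUE)
  scaled <- if (!is.na(dmax) && dmax > 0) d / dmax else d * 0
  out <- list(pearson_r = r, distance = d, scaled_distance = scaled)
  class(out) <- "similarity_result"
  out
}

#' @export
print.similarity_result <- function(x, ...) {
  cat("Adhesion-profile similarity (Pearson r):\n")
  print(round(x$pearson_r, 3))
  cat("Correlation distance (1 - r), scaled to the most dissimilar pair:\n")
  print(round(x$scaled_distance, 3))
  invisible(x)
}

#' Per-composition adhesion tests against a reference
#'
#' For each composition, a two-sided Welch t-test of the condition's
#' replicate counts against the reference condition's, with the normalised
#' effect (condition mean / reference mean) and its direction. Compositions
#' with fewer than two replicates in either group are skipped and flagged.
#' No multiple-testing adjustment is applied by default (per-test
#' significance at `alpha`); `adjust = "BH"` flags on
#' Benjamini-Hochberg-adjusted p-values instead, leaving the p-values
#' themselves untouched.
#'
#' @param x an `adhesion_matrix`.
#' @param condition,reference condition labels to compare.
#' @param alpha significance level for the flag (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return a `composition_tests` data frame: `composition`, `effect`,
#'   `p_value`, `q_value` (BH, reported regardless of `adjust`),
#'   `significant`, `direction` (+1 / -1 / 0), `tested`.
#' @export
compare_compositions <- function(x, condition, reference, alpha = 0.05,
                                 adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  check_adhesion(x)
  if (!all(c(condition, reference) %in% x$condition))
    stop_param("condition or reference not present in the data")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop_param("'alpha' must lie in (0, 1]")
  comps <- sort(unique(x$composition))
  rows <- lapply(comps, function(cm) {
    a <- x$count[x$condition == condition & x$composition == cm]
    b <- x$count[x$condition == reference & x$composition == cm]
    if (length(a) < 2L || length(b) < 2L)
      return(data.frame(composition = cm, effect = NA_real_,
                        p_value = NA_real_, tested = FALSE))
    eff <- if (mean(b) > 0) mean(a) / mean(b) else NA_real_
    p <- if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else {
      stats::t.test(a, b)$p.value
    }
    data.frame(composition = cm, effect = eff, p_value = p, tested = TRUE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  out$q_value[out$tested] <- stats::p.adjust(out$p_value[out$tested],
                                             method = "BH")
  crit <- if (adjust == "BH") out$q_value else out$p_value
  out$significant <- !is.na(crit) & crit <= alpha
  out$direction <- ifelse(is.na(out$effect), 0L, sign(out$effect - 1))
  class(out) <- c("composition_tests", "data.frame")
  out
}
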