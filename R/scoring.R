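# Druglikeness / Drug Score aggregation, Total Score, ADMET k-means
# clustering, and the cluster-distance-based Total Score 2.

#' Sigmoid descriptor component
#'
#' s = 1 / (1 + exp(a*p + b)), the contribution of one physicochemical
#' descriptor p (logP, logS, MW or druglikeness d) to the Drug Score.
#'
#' @param p descriptor value(s).
#' @param a,b slope and offset of the descriptor's convention.
#' @return value(s) in (0, 1).
#' @examples
#' sigmoidComponent(500, a = 0.012, b = -6)  # 0.5 at the MW midpoint
#' @export
sigmoidComponent <- function(p, a, b) 1 / (1 + exp(a * p + b))

#' Fragment-based druglikeness
#'
#' d = sum(v_i) / n over the fragment scores v_i matched in a molecule. The
#' fragment library and its scores are caller-supplied (pluggable provider);
#' an empty match list contributes a zero sum.
#'
#' @param fragmentScores numeric vector of matched-fragment scores (may be
#'   empty).
#' @param n normalization count (>= 1).
#' @return single real.
#' @export
druglikeness <- function(fragmentScores, n) {
  stopifnot(is.numeric(n), length(n) == 1L)
  if (n < 1) stop("'n' must be >= 1")
  sum(fragmentScores) / n
}

#' Per-descriptor sigmoid parameters
#'
#' (a, b) pairs for logP, logS, MW and druglikeness d.
#' \code{"datawarrior"} (default) orients every sigmoid so that favorable
#' values score high: (1, -5) logP, (-1, -5) logS, (0.012, -6) MW, (-1, 0)
#' d. \code{"printed"} is the literal alternative convention {1, -5},
#' {1, 5}, {0.012, 6}, {1, 0}.
#'
#' @param convention \code{"datawarrior"} or \code{"printed"}.
#' @return named list of \code{c(a, b)} pairs.
#' @export
drugScoreParams <- function(convention = c("datawarrior", "printed")) {
  convention <- match.arg(convention)
  if (convention == "datawarrior")
    list(logP = c(a = 1, b = -5), logS = c(a = -1, b = -5),
         mw = c(a = 0.012, b = -6), d = c(a = -1, b = 0))
  else
    list(logP = c(a = 1, b = -5), logS = c(a = 1, b = 5),
         mw = c(a = 0.012, b = 6), d = c(a = 1, b = 0))
}

.TOXICITY_WEIGHTS <- c(none = 1.0, low = 0.8, high = 0.6)
.RISK_CATEGORIES <- c("irritation", "mutagenic", "reproductive", "tumorigenic")

#' Drug Score of one compound
#'
#' dS = prod over descriptors of (1/2 + s_i/2), times prod over the four
#' toxicity categories of t_i, with t = 1.0 / 0.8 / 0.6 for no, low and high
#' risk. Always in (0, 1].
#'
#' @param logP,logS,mw,d descriptor values (mw in Da).
#' @param risks named character vector over exactly
#'   \code{c("irritation", "mutagenic", "reproductive", "tumorigenic")} with
#'   levels \code{"none"}, \code{"low"}, \code{"high"}.
#' @param params per-descriptor (a, b) pairs, see [drugScoreParams()].
#' @param toxicityWeights named weights for the three risk levels.
#' @return single real in (0, 1].
#' @examples
#' drugScore(logP = 2, logS = -3, mw = 350, d = 1,
#'           risks = c(irritation = "none", mutagenic = "none",
#'                     reproductive = "none", tumorigenic = "none"))
#' @export
drugScore <- function(logP, logS, mw, d,
                      risks = stats::setNames(rep("none", 4), .RISK_CATEGORIES),
                      params = drugScoreParams(),
                      toxicityWeights = .TOXICITY_WEIGHTS) {
  stopifnot(mw > 0, setequal(names(risks), .RISK_CATEGORIES),
            all(c("logP", "logS", "mw", "d") %in% names(params)))
  bad <- setdiff(unique(risks), names(toxicityWeights))
  if (length(bad))
    stop("unknown risk level(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(names(toxicityWeights), collapse = "/"), ")")
  p <- c(logP = logP, logS = logS, mw = mw, d = d)
  s <- vapply(names(p), function(k)
    sigmoidComponent(p[[k]], params[[k]]["a"], params[[k]]["b"]), numeric(1))
  prod(0.5 + 0.5 * s) * prod(toxicityWeights[risks])
}

#' Drug Scores for a descriptor table
#'
#' Row-wise [drugScore()] over a data.frame with columns \code{compound_id},
#' \code{logP}, \code{logS}, \code{mw}, \code{d} and the four risk columns
#' \code{irritation}, \code{mutagenic}, \code{reproductive},
#' \code{tumorigenic}.
#'
#' @param descriptors the descriptor data.frame.
#' @inheritParams drugScore
#' @return the input with a \code{dS} column appended.
#' @export
computeDrugScores <- function(descriptors, params = drugScoreParams(),
                              toxicityWeights = .TOXICITY_WEIGHTS) {
  need <- c("compound_id", "logP", "logS", "mw", "d", .RISK_CATEGORIES)
  miss <- setdiff(need, names(descriptors))
  if (length(miss))
    stop("descriptor table is missing column(s): ", paste(miss, collapse = ", "))
  descriptors$dS <- vapply(seq_len(nrow(descriptors)), function(i) {
    r <- descriptors[i, ]
    drugScore(r$logP, r$logS, r$mw, r$d,
              risks = stats::setNames(as.character(r[.RISK_CATEGORIES]),
                                      .RISK_CATEGORIES),
              params = params, toxicityWeights = toxicityWeights)
  }, numeric(1))
  descriptors
}

#' Total Score
#'
#' The product dS * S/N, combining druglikeness (Drug Score) with spectral
#' interaction specificity; both factors favor higher values.
#'
#' @param dS Drug Score(s) in (0, 1].
#' @param snr signal-to-noise ratio(s), >= 0.
#' @return dS * snr.
#' @export
totalScore <- function(dS, snr) {
  stopifnot(all(dS >= 0), all(snr >= 0))
  dS * snr
}

#' k-means clustering of an ADMET feature table
#'
#' Standardizes the numeric features (constant columns are dropped with a
#' warning), then runs k-means with \code{restarts} random initializations
#' under \code{seed}, keeping the best-inertia solution. Distances to the own
#' cluster centroid are Euclidean in the standardized space.
#'
#' @param table data.frame with a \code{compound_id} column plus numeric
#'   features (Yes/No fields already mapped to 1/0), or a numeric matrix with
#'   row names.
#' @param k number of clusters.
#' @param restarts random initializations (k-means \code{nstart}).
#' @param seed RNG seed.
#' @return list with \code{assignments} (data.frame: \code{compound_id},
#'   \code{cluster}, \code{centroidDistance}), \code{withinPct},
#'   \code{betweenPct} (variance decomposition, summing to 100),
#'   \code{centers} (standardized-space centroids), and the dropped constant
#'   columns in \code{droppedColumns}.
#' @export
clusterAdmet <- function(table, k = 5L, restarts = 10L, seed = 42L) {
  if (is.data.frame(table)) {
    if (!"compound_id" %in% names(table))
      stop("ADMET table needs a 'compound_id' column")
    ids <- as.character(table$compound_id)
    x <- as.matrix(table[setdiff(names(table), "compound_id")])
  } else {
    x <- as.matrix(table)
    ids <- rownames(x)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  }
  if (!is.numeric(x)) stop("ADMET features must be numeric")
  if (anyNA(x)) stop("ADMET table contains missing values")
  if (nrow(x) < k) stop("need at least k rows to form k clusters")
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (!ncol(x)) stop("no non-constant features remain")
  z <- scale(x)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (k == nrow(z)) {
    # every row is its own centroid; kmeans itself rejects this boundary case
    km <- list(cluster = seq_len(nrow(z)), centers = z,
               totss = sum(scale(z, scale = FALSE)^2),
               tot.withinss = 0)
    km$betweenss <- km$totss
  } else {
    km <- stats::kmeans(z, centers = k, nstart = restarts, iter.max = 100L)
  }
  dist <- sqrt(rowSums((z - km$centers[km$cluster, , drop = FALSE])^2))
  list(assignments = data.frame(compound_id = ids,
                                cluster = km$cluster,
                                centroidDistance = dist,
                                row.names = NULL),
       withinPct = 100 * km$tot.withinss / km$totss,
       betweenPct = 100 * km$betweenss / km$totss,
       centers = km$centers,
       droppedColumns = dropped)
}

#' Total Score 2
#'
#' S/N divided by the distance to the compound's ADMET cluster centroid:
#' favors spectrally specific compounds near the center of a pharmacokinetic
#' chemotype. A zero distance (a compound sitting exactly on its centroid)
#' is returned as \code{Inf}-free: the value is \code{NA} with
#' \code{rankFirst = TRUE}, to be placed ahead of all finite scores.
#'
#' @param snr signal-to-noise ratio(s).
#' @param centroidDistance distance(s) to the own cluster centroid.
#' @return data.frame with \code{totalScore2} and \code{rankFirst}.
#' @export
totalScore2 <- function(snr, centroidDistance) {
  stopifnot(length(snr) == length(centroidDistance),
            all(snr >= 0), all(centroidDistance >= 0))
  zero <- centroidDistance == 0
  out <- data.frame(totalScore2 = ifelse(zero, NA_real_,
                                         snr / centroidDistance),
                    rankFirst = zero)
  out
}
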