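#' Global explained variance of a template assignment
#'
#' GEV is the GFP-squared-weighted share of topographic variance explained by
#' the assigned templates:
#' `GEV = sum_t (w_t * C(u_t, T_a(t)))^2 / sum_t w_t^2`,
#' where `w_t` is the GFP of map t, `C` the absolute spatial correlation, and
#' `a(t)` the template assigned to map t. The result lies in `[0, 1]`.
#'
#' @param maps Channels x M matrix of topographic maps (columns).
#' @param gfp_weights GFP weights, one per map; defaults to equal weights.
#' @param templates [template_set()] or channels x K matrix.
#' @param assignment Integer vector mapping each map to a template column.
#' @return GEV fraction in `[0, 1]`.
#' @examples
#' t1 <- normalize_maps(matrix(rnorm(8), 8, 1))
#' gev(cbind(t1, -2 * t1), templates = t1, assignment = c(1, 1)) # exactly 1
#' @export
gev <- function(maps, gfp_weights = NULL, templates, assignment) {
  maps <- as.matrix(maps)
  m <- ncol(maps)
  gfp_weights <- gfp_weights %||% rep(1, m)
  if (length(gfp_weights) != m) stop_dimension("`gfp_weights` must have one weight per map.")
  if (all(gfp_weights == 0)) stop_undefined("total GFP is zero; GEV is undefined.")
  if (length(assignment) != m) stop_dimension("`assignment` must map every map to a template.")
  tm <- normalize_maps(as_template_matrix(templates))
  mn <- normalize_maps(maps)
  corr <- abs(colSums(mn * tm[, assignment, drop = FALSE]))
  sum((gfp_weights * corr)^2) / sum(gfp_weights^2)
}

#' Atomize-and-agglomerate hierarchical clustering of topographic maps
#'
#' AAHC for microstate estimation. Every map starts as its own cluster;
#' while more than `k_target` clusters remain, one cluster is dissolved
#' ("atomized") and each of its maps is reassigned to the surviving cluster
#' whose centroid it correlates with most strongly in absolute value.
#' Centroids are the sign-aligned, renormalized means of their members.
#'
#' The victim is the cluster whose disappearance costs the least global
#' explained variance. With the default `criterion = "cost"` this is
#' evaluated with reassignment look-ahead: the cluster's GEV contribution
#' minus the contribution its members would recover in the best surviving
#' clusters. This protects small tight clusters (a rare microstate in a short
#' epoch) and dissolves redundant near-duplicate clusters first; the plain
#' `"contribution"` rule (smallest current GEV contribution, no look-ahead)
#' is also available, but on short epochs it can permanently lose a rare
#' class even for noise-free data.
#'
#' Polarity is ignored throughout, so the result is invariant to flipping the
#' sign of any input map, and to positive rescaling of maps (maps are
#' normalized on entry). Ties break toward the lower cluster index, making
#' the procedure deterministic for a given input order.
#'
#' @param maps Channels x M matrix of maps (typically sampled at GFP peaks),
#'   or a list of map vectors.
#' @param k_target Desired number of microstate classes.
#' @param gfp_weights Optional GFP value of each map, used in the GEV
#'   criterion; defaults to equal weights.
#' @param criterion Victim-selection rule: `"cost"` (default) or
#'   `"contribution"`.
#' @param band Band tag carried into the result.
#' @return A [template_set()] (level `"trial"`) whose `gev` is the final GEV;
#'   the final cluster membership is stored in attribute `"assignment"`.
#' @export
aahc <- function(maps, k_target, gfp_weights = NULL,
                 criterion = c("cost", "contribution"), band = NA_character_) {
  criterion <- match.arg(criterion)
  if (is.list(maps)) maps <- do.call(cbind, maps)
  maps <- as.matrix(maps)
  m <- ncol(maps)
  if (k_target < 1 || k_target > m) {
    stop_invalid("`k_target` must lie between 1 and the number of maps.")
  }
  w <- gfp_weights %||% rep(1, m)
  if (length(w) != m) stop_dimension("`gfp_weights` must have one weight per map.")
  u <- normalize_maps(maps)

  members <- as.list(seq_len(m))
  cent <- u
  total_w2 <- sum(w^2)

  while (length(members) > k_target) {
    cross <- abs(crossprod(cent, u)) # clusters x maps
    contrib <- vapply(seq_along(members), function(i) {
      sum((w[members[[i]]] * cross[i, members[[i]]])^2)
    }, numeric(1))
    score <- if (criterion == "contribution" || length(members) == 1L) {
      contrib
    } else {
      ## removal cost: contribution lost minus what the members recover in
      ## the best surviving cluster
      vapply(seq_along(members), function(i) {
        idx <- members[[i]]
        other <- apply(cross[-i, idx, drop = FALSE], 2, max)
        contrib[i] - sum((w[idx] * other)^2)
      }, numeric(1))
    }
    victim <- which.min(score) # ties: lowest index
    freed <- members[[victim]]
    members[[victim]] <- NULL
    cent <- cent[, -victim, drop = FALSE]
    ## reassign freed maps to the best remaining centroid
    corr <- abs(crossprod(cent, u[, freed, drop = FALSE]))
    dest <- apply(corr, 2, which.max)
    touched <- unique(dest)
    for (j in seq_along(freed)) {
      members[[dest[j]]] <- c(members[[dest[j]]], freed[j])
    }
    for (cl in touched) {
      cent[, cl] <- cluster_centroid(u, members[[cl]], cent[, cl])
    }
  }

  assignment <- integer(m)
  for (i in seq_along(members)) assignment[members[[i]]] <- i
  out <- template_set(cent, level = "trial", band = band)
  out$gev <- min(1, max(0, gev(u, w, out, assignment)))
  attr(out, "assignment") <- assignment
  out
}

## Sign-aligned, renormalized mean of member maps. Members are flipped to
## correlate positively with the current centroid before averaging; the
## centroid sign is canonicalized (largest-magnitude channel positive).
cluster_centroid <- function(u, idx, current) {
  sub <- u[, idx, drop = FALSE]
  s <- sign(colSums(sub * current))
  s[s == 0] <- 1
  v <- as.vector(sub %*% s) / length(idx)
  n <- sqrt(sum(v^2))
  if (n == 0) {
    return(current)
  }
  v <- v / n
  i <- which.max(abs(v))
  if (v[i] < 0) v <- -v
  v
}
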