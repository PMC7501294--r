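# Neighbourhood graph over fibre centroids and the hypergeometric test for
# spatial clustering of deficient fibres.

#' Effective radius of a fibre
#'
#' Radius of the circle with the same area as the fibre cross-section:
#' `sqrt(area / pi)`. At IMC resolution areas are um^2, so the radius is
#' in um (= px).
#'
#' @param area Fibre area(s) in px^2, strictly positive.
#' @return Numeric vector of radii in px.
#' @examples
#' effective_radius(100)  # 5.6419
#' @export
effective_radius <- function(area) {
  if (any(area <= 0)) abort("area must be > 0")
  sqrt(area / pi)
}

#' Build the fibre neighbourhood graph
#'
#' Two fibres are neighbours when their centroids lie within
#' `multiplier` times the sample's average effective radius of each other
#' (default five times, roughly 2.5 fibre diameters). The graph is
#' symmetric with no self-loops.
#'
#' @param fibres Data frame with centroid columns `x`, `y` (px) and
#'   `area` (px^2); an optional `fibre` id column is carried through.
#' @param multiplier Threshold multiplier on the mean effective radius.
#'
#' @return An object of class `neighbour_graph`: fields `id`, `x`, `y`,
#'   `r_eff_mean`, `threshold` (px) and `adj` (adjacency list of integer
#'   node indices).
#' @export
build_neighbour_graph <- function(fibres, multiplier = 5) {
  need <- c("x", "y", "area")
  if (!all(need %in% names(fibres))) {
    abort("fibres must have x, y and area columns")
  }
  if (nrow(fibres) < 2) abort("need at least 2 fibres")
  if (any(!is.finite(fibres$x) | !is.finite(fibres$y))) {
    abort("missing centroids")
  }
  r <- effective_radius(fibres$area)
  thr <- multiplier * mean(r)
  d <- as.matrix(stats::dist(cbind(fibres$x, fibres$y)))
  a <- d <= thr
  diag(a) <- FALSE
  adj <- lapply(seq_len(nrow(a)), function(i) which(a[i, ]))
  structure(list(id = fibres[["fibre"]] %||% seq_len(nrow(fibres)),
                 x = fibres$x, y = fibres$y,
                 r_eff_mean = mean(r), threshold = thr,
                 n = nrow(fibres), adj = adj),
            class = "neighbour_graph")
}

#' @export
print.neighbour_graph <- function(x, ...) {
  cat(sprintf("<neighbour_graph> %d fibres, threshold %.1f px (5 x r_eff %.1f), %d edges\n",
              x$n, x$threshold, x$r_eff_mean,
              sum(lengths(x$adj)) / 2))
  invisible(x)
}

#' @method tidy neighbour_graph
#' @export
tidy.neighbour_graph <- function(x, ...) {
  from <- rep(seq_len(x$n), lengths(x$adj))
  to <- unlist(x$adj)
  keep <- from < to
  tibble(from = x$id[from[keep]], to = x$id[to[keep]])
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` fibres
#' without replacement from `N` of which `K` are deficient. Computed as
#' the survival function at `k - 1`.
#'
#' @param N Population size.
#' @param K Number of "successes" (deficient fibres) in the population.
#' @param n Sample (neighbour-set) size.
#' @param k Observed successes in the sample.
#' @return Probability in `[0, 1]`.
#' @examples
#' hypergeom_upper(10, 5, 4, 4)  # 5/210
#' @export
hypergeom_upper <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n)) {
    abort("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Test for spatial enrichment of deficient fibres
#'
#' Tests whether deficient fibres are over-represented within the set of
#' fibres that are neighbours of deficient fibres. The neighbour set is
#' the union of the neighbourhoods of all deficient ("seed") fibres; a
#' deficient fibre never belongs to its own neighbourhood, but under the
#' default convention it may appear in the set as a neighbour of another
#' seed, so the test asks whether deficient fibres co-occur as each
#' other's neighbours more than chance predicts. With
#' `include_seeds = FALSE` all deficient fibres are removed from the
#' neighbour set and from the candidate population; with binary
#' deficiency labels there are then no deficient fibres left to find and
#' the test is degenerate (p = 1) — the option exists to make the
#' membership convention explicit and auditable.
#'
#' @param graph A [build_neighbour_graph()] result.
#' @param deficient Logical vector aligned with the graph's nodes.
#' @param include_seeds Membership convention for deficient fibres in the
#'   neighbour set (see Details); default `TRUE`.
#'
#' @return An object of class `enrichment_result` with fields `N`
#'   (population size), `K` (deficient in population), `n` (neighbour-set
#'   size), `k` (deficient in neighbour set), `p` (upper-tail
#'   hypergeometric probability) and `neighbour_set` (node indices).
#' @export
neighbourhood_enrichment <- function(graph, deficient, include_seeds = TRUE) {
  stopifnot(inherits(graph, "neighbour_graph"))
  if (length(deficient) != graph$n) {
    abort("deficient flags must align with graph nodes")
  }
  seeds <- which(deficient)
  nb <- sort(unique(unlist(graph$adj[seeds])))
  if (include_seeds) {
    N <- graph$n; K <- length(seeds)
  } else {
    nb <- setdiff(nb, seeds)
    N <- graph$n - length(seeds)
    K <- 0L
  }
  n <- length(nb)
  k <- if (include_seeds) sum(deficient[nb]) else 0L
  p <- if (length(seeds) == 0 || n == 0) 1 else hypergeom_upper(N, K, n, k)
  structure(list(N = N, K = K, n = n, k = k, p = p,
                 include_seeds = include_seeds, neighbour_set = nb),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> k = %d deficient among n = %d neighbours (K = %d of N = %d); p = %.4g\n",
              x$k, x$n, x$K, x$N, x$p))
  invisible(x)
}

#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(N = x$N, K = x$K, n = x$n, k = x$k, p.value = x$p,
         include_seeds = x$include_seeds)
}
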