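#' Build a bipartite interaction web from pair records
#'
#' @param interactions Either a two-column data frame / matrix of
#'   (primary taxon, hyperparasitoid taxon) labels or a list of length-2
#'   vectors. Counts the multiplicity of each pair.
#' @return An object of class `bipartite_web`: integer count matrix `a`
#'   (primary rows x hyperparasitoid columns), taxa ordered canonically
#'   (vocabulary order for known taxa, then alphabetical), with total `m` and
#'   marginals `r`, `c`.
#' @export
build_web <- function(interactions) {
  if (is.list(interactions) && !is.data.frame(interactions))
    interactions <- do.call(rbind, interactions)
  interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
  if (!nrow(interactions)) stop("empty interaction list")
  p <- as.character(interactions[[1]])
  h <- as.character(interactions[[2]])
  canon <- function(x, vocab) {
    lev <- c(intersect(vocab, x), sort(setdiff(unique(x), vocab)))
    factor(x, levels = lev)
  }
  pf <- canon(p, PRIMARY_TAXA)
  hf <- canon(h, HYPER_TAXA)
  a <- table(pf, hf)
  a <- matrix(as.integer(a), nrow = nlevels(pf),
              dimnames = list(levels(pf), levels(hf)))
  new_web(a)
}

new_web <- function(a) {
  storage.mode(a) <- "integer"
  structure(list(a = a, m = sum(a), r = rowSums(a), c = colSums(a),
                 row_taxa = rownames(a), col_taxa = colnames(a)),
            class = "bipartite_web")
}

as_web <- function(web) {
  if (inherits(web, "bipartite_web")) return(web)
  if (is.matrix(web)) {
    if (is.null(rownames(web))) rownames(web) <- paste0("P", seq_len(nrow(web)))
    if (is.null(colnames(web))) colnames(web) <- paste0("H", seq_len(ncol(web)))
    return(new_web(web))
  }
  stop("expected a bipartite_web or a count matrix")
}

#' @export
print.bipartite_web <- function(x, ...) {
  cat("Bipartite web:", nrow(x$a), "x", ncol(x$a), "taxa, m =", x$m, "\n")
  print(x$a)
  invisible(x)
}

# entropy (nats) of a count/weight vector summing to m:
# H = log m - sum(v log v)/m; zero cells contribute nothing
entropy_weights <- function(v, m = sum(v)) {
  v <- v[v > 0]
  log(m) - sum(v * log(v)) / m
}

#' Joint Shannon entropy of an interaction web
#'
#' `H2 = -sum p_ij log p_ij` in nats, with `p_ij = a_ij / m`; empty cells
#' contribute zero.
#'
#' @param web A `bipartite_web` or count matrix with at least one interaction.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(web) {
  web <- as_web(web)
  if (web$m <= 0) stop("web has no interactions (m = 0)")
  entropy_weights(as.numeric(web$a), web$m)
}

#' Entropy bounds of a web given its marginal totals
#'
#' Computes heuristic minimum and maximum joint entropies achievable by webs
#' sharing the observed marginals. In `integer` mode both bounds are
#' entropies of actual integer matrices with the observed marginals, so they
#' are inner bounds of the exact extrema: the maximum allocates the m
#' interactions toward the expected counts `r_i c_j / m` and is exact (the
#' integer matrix minimizing `sum a log a`, found by successive
#' shortest-path augmentation with convex unit costs); the minimum comes
#' from a portfolio of greedy concentration algorithms (the classical
#' largest-row-with-largest-column pairing with ties broken at the lowest
#' index, a variant that first forms perfect blocks from exactly matching
#' marginals, and a one-step lookahead on the largest row), taking the most
#' concentrated allocation found. In `continuous` mode the maximum is the
#' independence entropy `H(r/m) + H(c/m)` and the minimum the classical
#' greedy algorithm run on real-valued marginals.
#'
#' @param web A `bipartite_web` or count matrix.
#' @param mode `"integer"` (default, the convention used for count webs) or
#'   `"continuous"`.
#' @return Named numeric vector `c(H2min, H2max)` in nats.
#' @export
entropy_bounds <- function(web, mode = c("integer", "continuous")) {
  web <- as_web(web)
  mode <- match.arg(mode)
  if (web$m <= 0) stop("web has no interactions (m = 0)")
  r <- web$r[web$r > 0]
  cc <- web$c[web$c > 0]
  m <- web$m
  if (mode == "integer") {
    c(H2min = log(m) - cpp_conc_min_S(r, cc) / m,
      H2max = entropy_weights(as.numeric(cpp_spread_max_alloc(r, cc)), m))
  } else {
    c(H2min = entropy_weights(greedy_min_alloc(r, cc, integer_mode = FALSE), m),
      H2max = entropy_weights(r, m) + entropy_weights(cc, m))
  }
}

# greedy concentration: cell values of a maximally concentrated allocation
greedy_min_alloc <- function(r, cc, integer_mode = TRUE) {
  eps <- if (integer_mode) 0.5 else 1e-12 * sum(r)
  vals <- numeric(0)
  while (sum(r) > eps) {
    i <- which.max(r)
    j <- which.max(cc)
    v <- min(r[i], cc[j])
    vals <- c(vals, v)
    r[i] <- r[i] - v
    cc[j] <- cc[j] - v
  }
  vals
}

#' Standardized network-level specialization H2'
#'
#' `H2' = (H2max - H2) / (H2max - H2min)`, clamped to \[0, 1\]: 0 means the
#' web equals the maximum-entropy (independence-like) allocation, 1 a
#' perfectly specialized one-to-one web. Degenerate webs whose marginals
#' force a single allocation (single row, single column, or
#' `H2max - H2min < eps`) return 0 by convention.
#'
#' @inheritParams entropy_bounds
#' @param eps Degeneracy threshold on `H2max - H2min` (default 1e-12).
#' @return H2' in \[0, 1\].
#' @export
h2_prime <- function(web, mode = c("integer", "continuous"), eps = 1e-12) {
  idx <- h2_indices(web, mode, eps)
  idx$H2prime
}

#' All members of the H2 entropy family
#'
#' @inheritParams h2_prime
#' @return List with `H2`, `H2min`, `H2max`, `H2prime` and `mode`.
#' @export
h2_indices <- function(web, mode = c("integer", "continuous"), eps = 1e-12) {
  web <- as_web(web)
  mode <- match.arg(mode)
  h2 <- shannon_entropy(web)
  b <- entropy_bounds(web, mode)
  span <- b[["H2max"]] - b[["H2min"]]
  h2p <- if (span < eps) 0 else min(1, max(0, (b[["H2max"]] - h2) / span))
  list(H2 = h2, H2min = b[["H2min"]], H2max = b[["H2max"]],
       H2prime = h2p, mode = mode)
}

#' Exact entropy extrema by exhaustive enumeration
#'
#' Enumerates every nonnegative integer matrix with the given row and column
#' totals and returns the exact minimum and maximum joint entropy. Intended
#' as a test oracle for the heuristic bounds; the enumeration budget guards
#' against combinatorial explosion.
#'
#' @param r,cc Integer row and column marginal totals (equal sums).
#' @param budget Maximum total count m accepted (default 12).
#' @return Named vector `c(min, max)` of exact entropies in nats, with the
#'   number of matrices enumerated as attribute `n_matrices`.
#' @export
exact_bounds_oracle <- function(r, cc, budget = 12L) {
  r <- as.integer(r)
  cc <- as.integer(cc)
  m <- sum(r)
  if (sum(cc) != m) stop("row and column totals must have equal sums")
  if (m < 1) stop("m must be positive")
  if (m > budget)
    stop("m = ", m, " exceeds the enumeration budget (", budget,
         "); use the heuristic entropy_bounds() instead")
  nlogn <- c(0, seq_len(m) * log(seq_len(m)))  # v*log(v) at index v+1
  env <- new.env()
  env$smin <- Inf    # extrema of sum a*log(a): H = log m - S/m
  env$smax <- -Inf
  env$count <- 0
  nr <- length(r)
  nc <- length(cc)
  rec <- function(ri, cc_left, S) {
    if (ri == nr) {  # last row forced by remaining column totals
      S <- S + sum(nlogn[cc_left + 1L])
      env$count <- env$count + 1
      if (S < env$smin) env$smin <- S
      if (S > env$smax) env$smax <- S
      return(invisible())
    }
    target <- r[ri]
    row <- integer(nc)
    comp <- function(j, rem, Srow) {
      if (j == nc) {
        if (rem <= cc_left[nc]) {
          row[nc] <<- rem
          rec(ri + 1L, cc_left - row, S + Srow + nlogn[rem + 1L])
          row[nc] <<- 0L
        }
        return(invisible())
      }
      for (v in 0:min(rem, cc_left[j])) {
        row[j] <<- v
        comp(j + 1L, rem - v, Srow + nlogn[v + 1L])
      }
      row[j] <<- 0L
    }
    comp(1L, target, 0)
  }
  rec(1L, cc, 0)
  out <- c(min = log(m) - env$smax / m, max = log(m) - env$smin / m)
  attr(out, "n_matrices") <- env$count
  out
}
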