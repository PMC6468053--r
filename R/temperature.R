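# Matrix-temperature nestedness (Rodriguez-Girones & Santamaria 2006).
#
# The temperature of a packed binary matrix measures its departure from
# perfect nestedness. Cell centers are mapped onto the unit square; an
# isocline of perfect nestedness for the observed fill separates the region
# where presences are expected from the region where absences are expected;
# each misplaced cell contributes the square of its normalized distance from
# the isocline, measured along the cell's 45-degree diagonal, and the sum is
# rescaled by U_max = 0.04145 so that T lies in [0, 100]. Packing (the row
# and column ordering) is chosen to minimize T.

.UMAX <- 0.04145

# Isocline of perfect nestedness for fill parameter p.
.isocline <- function(x, p) 1 - (1 - (1 - x)^p)^(1/p)

# Solve the fill parameter p so that the area under the isocline equals the
# matrix fill. Fixed-grid Simpson evaluation keeps the root deterministic.
.fill_parameter <- function(fill) {
  grid <- seq(0, 1, length.out = 2001L)
  w <- c(1, rep(c(4, 2), length.out = length(grid) - 2L), 1)
  area <- function(p) sum(w * .isocline(grid, p)) * (grid[2L] - grid[1L]) / 3
  stats::uniroot(function(p) area(p) - fill, c(1e-8, 50),
                 extendInt = "downX", tol = 1e-10)$root
}

# Position-wise unexpectedness weights for an n x m matrix with the given
# fill: Wpres[i, j] is the penalty if cell (i, j) holds a presence, Wabs the
# penalty if it holds an absence. Depends only on shape and fill, so one
# evaluation serves every candidate ordering of the same matrix.
.temperature_weights <- function(n, m, fill) {
  r <- (seq_len(n) - 0.5) / n
  cc <- (seq_len(m) - 0.5) / m
  p <- .fill_parameter(fill)
  totdis <- 1 - abs(outer(r, cc, "-"))
  iso_x <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    a <- cc[j] - r[i]
    iso_x[i, j] <- stats::uniroot(function(x) .isocline(x, p) - a - x,
                                  c(0, 1), tol = 1e-10)$root
  }
  u <- (r - iso_x) / totdis   # r recycles down columns
  list(Wpres = pmax(u, 0)^2,  # presence below/right of the isocline
       Wabs  = pmin(u, 0)^2)  # absence above/left of the isocline
}

# Temperature of a fixed ordering, given precomputed weights.
.temperature_score <- function(m, w) {
  100 * sum(ifelse(m == 1L, w$Wpres, w$Wabs)) / length(m) / .UMAX
}

# Score an ordering via the presence-cell decomposition:
#   T = K + sum over presence cells of D[rowpos, colpos]
# with D = Wpres - Wabs and K = sum(Wabs). `pr`/`pc` are presence-cell
# subscripts in the matrix's input labeling.
.order_score_fun <- function(m, w) {
  D <- w$Wpres - w$Wabs
  K <- sum(w$Wabs)
  pres <- which(m == 1L, arr.ind = TRUE)
  scale <- 100 / (length(m) * .UMAX)
  function(rowpos, colpos) {
    scale * (K + sum(D[cbind(rowpos[pres[, 1L]], colpos[pres[, 2L]])]))
  }
}

# Degree-sort packing: rows by decreasing degree, columns by decreasing
# degree, ties broken by the binary pattern so the start is deterministic.
.degree_positions <- function(m) {
  rkey <- apply(m, 1L, paste, collapse = "")
  ckey <- apply(m, 2L, paste, collapse = "")
  list(rowpos = order(order(-rowSums(m), rkey)),
       colpos = order(order(-colSums(m), ckey)))
}

.perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Nestedness matrix temperature
#'
#' Minimizes the packed-matrix temperature over row and column orderings.
#' For matrices with at most 5 rows and 5 columns every ordering is
#' enumerated, so the reported minimum is exact; larger matrices are packed
#' by decreasing degree and refined by seeded stochastic swap hill-climbing
#' with restarts. Input row/column order never affects the result: the
#' search always starts from the same canonical packing.
#'
#' @param m an [incidence_matrix()] (or plain 0/1 matrix), at least 2x2, no
#'   all-zero rows or columns.
#' @param seed integer seed for the stochastic search.
#' @param effort `"fast"` or `"thorough"` search preset (restarts x sweep
#'   iterations), or a list with elements `restarts` and `iter`.
#' @return A list with `temperature` (T in `[0, 100]`), `nestedness`
#'   (`(100 - T)/100`), `row_order` and `col_order` (packing that attains T,
#'   as indices into the input), and `fill`.
#' @examples
#' stair <- lower.tri(diag(4), diag = TRUE) + 0
#' dimnames(stair) <- list(paste0("i", 1:4), paste0("r", 1:4))
#' matrix_temperature(incidence_matrix(stair))$temperature  # 0
#' @export
matrix_temperature <- function(m, seed = 1L, effort = "fast") {
  m <- unclass(m)
  storage.mode(m) <- "integer"
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("undefined temperature: matrix smaller than 2x2")
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L))
    stop("temperature needs a matrix without all-zero rows/columns")
  n <- nrow(m); k <- ncol(m)
  fill <- sum(m) / (n * k)
  if (fill == 1) {
    return(list(temperature = 0, nestedness = 1,
                row_order = seq_len(n), col_order = seq_len(k), fill = fill))
  }
  w <- .temperature_weights(n, k, fill)
  score <- .order_score_fun(m, w)

  if (n <= 5L && k <= 5L) {
    rp <- .perms(n); cp <- .perms(k)
    best <- Inf; best_r <- rp[1L, ]; best_c <- cp[1L, ]
    for (a in seq_len(nrow(rp))) {
      rpos <- order(rp[a, ])  # positions of input rows
      for (b in seq_len(nrow(cp))) {
        cpos <- order(cp[b, ])
        s <- score(rpos, cpos)
        if (s < best) { best <- s; best_r <- rp[a, ]; best_c <- cp[b, ] }
      }
    }
    best <- max(0, min(100, best))
    return(list(temperature = best, nestedness = (100 - best) / 100,
                row_order = best_r, col_order = best_c, fill = fill))
  }

  preset <- if (is.list(effort)) effort
            else switch(match.arg(effort, c("fast", "thorough")),
                        fast = list(restarts = 4L, iter = 60L * (n + k)),
                        thorough = list(restarts = 16L, iter = 250L * (n + k)))
  # presence-cell sum with O(degree) delta updates on row/column swaps
  D <- (w$Wpres - w$Wabs)
  Jrow <- apply(m == 1L, 1L, which, simplify = FALSE)
  Jcol <- apply(m == 1L, 2L, which, simplify = FALSE)
  psum <- function(rpos, cpos) {
    pres <- which(m == 1L, arr.ind = TRUE)
    sum(D[cbind(rpos[pres[, 1L]], cpos[pres[, 2L]])])
  }
  deg <- .degree_positions(m)
  best <- Inf; best_rpos <- deg$rowpos; best_cpos <- deg$colpos
  with_seed(seed, {
    for (rs in seq_len(preset$restarts)) {
      if (rs == 1L) {
        rpos <- deg$rowpos; cpos <- deg$colpos
      } else {
        rpos <- sample.int(n); cpos <- sample.int(k)
      }
      cur <- psum(rpos, cpos)
      flip_row <- stats::runif(preset$iter) < 0.5
      for (it in seq_len(preset$iter)) {
        if (flip_row[it]) {
          sw <- sample.int(n, 2L)
          p1 <- rpos[sw[1L]]; p2 <- rpos[sw[2L]]
          c1 <- cpos[Jrow[[sw[1L]]]]; c2 <- cpos[Jrow[[sw[2L]]]]
          d <- sum(D[p2, c1] - D[p1, c1]) + sum(D[p1, c2] - D[p2, c2])
          if (d < 0) { cur <- cur + d; rpos[sw] <- c(p2, p1) }
        } else {
          sw <- sample.int(k, 2L)
          p1 <- cpos[sw[1L]]; p2 <- cpos[sw[2L]]
          r1 <- rpos[Jcol[[sw[1L]]]]; r2 <- rpos[Jcol[[sw[2L]]]]
          d <- sum(D[r1, p2] - D[r1, p1]) + sum(D[r2, p1] - D[r2, p2])
          if (d < 0) { cur <- cur + d; cpos[sw] <- c(p2, p1) }
        }
      }
      if (cur < best) { best <- cur; best_rpos <- rpos; best_cpos <- cpos }
    }
  })
  best <- 100 * (sum(w$Wabs) + best) / (n * k * .UMAX)
  best <- max(0, min(100, best))
  list(temperature = best, nestedness = (100 - best) / 100,
       row_order = order(best_rpos), col_order = order(best_cpos),
       fill = fill)
}

#' Nestedness from temperature
#'
#' Rescales matrix temperature onto the 0-1 nestedness scale used for
#' reporting: `N = (100 - T) / 100`, so a perfectly nested matrix (T = 0)
#' has N = 1.
#'
#' @param temperature T in `[0, 100]`.
#' @return N in `[0, 1]`.
#' @export
nestedness <- function(temperature) {
  if (!is.numeric(temperature) || any(temperature < 0 | temperature > 100))
    stop("temperature must lie in [0, 100]")
  (100 - temperature) / 100
}
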