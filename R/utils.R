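# Internal helpers shared across modules.

#' Draw Laplace (double-exponential) deviates by SD
#'
#' Difference of two unit exponentials has a standard Laplace distribution;
#' rescaled so `sd` is the standard deviation (not the scale parameter).
#' Used for network baseline loadings: leptokurtic sources are what makes the
#' planted networks identifiable by ICA.
#' @keywords internal
#' @noRd
rlaplaceSd <- function(n, mean = 0, sd = 1) {
  mean + (stats::rexp(n) - stats::rexp(n)) * sd / sqrt(2)
}

#' Derive a stage seed from a global seed
#'
#' Deterministic, stays below 2^31 so it is a valid R integer seed.
#' @keywords internal
#' @noRd
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 16807) %% 2147483629)
}

#' Optimal assignment (Hungarian algorithm, square cost matrix)
#'
#' O(n^3) shortest-augmenting-path formulation with dual potentials.
#' Returns, for each row, the column index of the minimum-cost perfect
#' matching. Used to match ICA components between decompositions; exact,
#' unlike greedy matching, when correlation ties or near-ties occur.
#' @keywords internal
#' @noRd
hungarianMin <- function(a) {
  n <- nrow(a)
  m <- ncol(a)
  if (n != m) stop("hungarianMin() requires a square cost matrix")
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- -1L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- a[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) assignment[p[j + 1]] <- j
  assignment
}

#' Column means/SDs with the 1/n convention
#' @keywords internal
#' @noRd
colMeanSdN <- function(X) {
  m <- colMeans(X)
  s <- sqrt(colMeans(X^2) - m^2)
  # guard tiny negative from rounding
  s[s < 0 | !is.finite(s)] <- 0
  list(mean = m, sd = s)
}

#' Render numeric columns with 17 significant digits (exact round trip)
#' @keywords internal
#' @noRd
formatExact <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      x <- df[[j]]
      out <- sprintf("%.17g", x)
      out[is.na(x)] <- NA_character_
      df[[j]] <- out
    }
  }
  df
}

#' Stop with a compact listing of offending row/ids
#' @keywords internal
#' @noRd
rowsMsg <- function(ids, max_show = 8) {
  ids <- as.character(ids)
  shown <- utils::head(ids, max_show)
  extra <- length(ids) - length(shown)
  paste0(paste(shown, collapse = ", "),
         if (extra > 0) sprintf(" (+%d more)", extra) else "")
}
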