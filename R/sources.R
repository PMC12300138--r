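# Source apportionment: correlation screening, adequacy tests, PCA with
# varimax rotation, and an uncertainty-weighted positive matrix
# factorization solver run separately per layer.

#' Pearson correlation matrix with pairwise p-values
#'
#' @param x Numeric samples x metals matrix (>= 3 rows).
#' @return List with `r` (correlations) and `p` (two-sided p-values
#'   from the t distribution with n-2 df). Constant columns yield NA
#'   entries with a warning.
#' @export
pearson_matrix <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 samples")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "),
            " have undefined correlations")
  }
  r <- suppressWarnings(stats::cor(x))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  list(r = r, p = p, n = n)
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' `KMO = sum(r^2) / (sum(r^2) + sum(a^2))` over off-diagonal entries,
#' where `a` are the anti-image partial correlations obtained from the
#' inverse correlation matrix.
#'
#' @param r Correlation matrix (invertible).
#' @return KMO value in \code{[0, 1]}.
#' @export
kmo <- function(r) {
  r <- as.matrix(r)
  inv <- tryCatch(solve(r), error = function(e) {
    stop("correlation matrix is singular (condition number ",
         format(kappa(r), digits = 3), "); KMO undefined")
  })
  d <- 1 / sqrt(diag(inv))
  partial <- -inv * outer(d, d)
  off <- upper.tri(r)
  sum(r[off]^2) / (sum(r[off]^2) + sum(partial[off]^2))
}

#' Bartlett test of sphericity
#'
#' `chi2 = -(n - 1 - (2p + 5)/6) * ln det(R)` on `p(p-1)/2` degrees of
#' freedom, against the null of an identity correlation matrix.
#'
#' @param r Correlation matrix.
#' @param n Number of samples (must exceed the number of variables).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(r, n) {
  p <- ncol(r)
  if (n <= p) stop("Bartlett test requires n > number of variables")
  stat <- -(n - 1 - (2 * p + 5) / 6) * determinant(r)$modulus[1]
  df <- p * (p - 1) / 2
  list(statistic = as.numeric(stat), df = df,
       p_value = stats::pchisq(as.numeric(stat), df, lower.tail = FALSE))
}

#' PCA on the correlation matrix with varimax rotation
#'
#' Standardizes columns, eigendecomposes the correlation matrix,
#' retains components with eigenvalue > 1 and varimax-rotates the
#' retained loadings (Kaiser-normalized). KMO and Bartlett adequacy
#' diagnostics are reported, not enforced.
#'
#' @param x Samples x metals matrix.
#' @return List: `eigenvalues`, `n_retained`, `loadings` (rotated),
#'   `unrotated`, `scores` (regression method), `explained` (variance
#'   fractions of retained components, post-rotation), `kmo`,
#'   `bartlett`.
#' @export
pca_varimax <- function(x) {
  x <- as.matrix(x)
  R <- stats::cor(x)
  eig <- eigen(R, symmetric = TRUE)
  vals <- eig$values
  k <- sum(vals > 1)
  if (k < 1) {
    warning("no eigenvalue exceeds 1; retaining nothing")
    return(list(eigenvalues = vals, n_retained = 0L))
  }
  L <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k)
  rownames(L) <- colnames(x)
  colnames(L) <- paste0("PC", seq_len(k))
  if (k >= 2) {
    Lr <- best_varimax(L)
    # order rotated components by explained variance, fix sign so the
    # dominant loadings are positive
    ord <- order(colSums(Lr^2), decreasing = TRUE)
    Lr <- Lr[, ord, drop = FALSE]
    sgn <- ifelse(colSums(Lr^3) < 0, -1, 1)
    Lr <- sweep(Lr, 2, sgn, `*`)
    dimnames(Lr) <- dimnames(L)
  } else {
    Lr <- L
  }
  z <- scale(x)
  scores <- z %*% solve(R, Lr)
  bt <- bartlett_sphericity(R, nrow(x))
  list(eigenvalues = vals, n_retained = k, loadings = Lr, unrotated = L,
       scores = scores, explained = colSums(Lr^2) / ncol(x),
       kmo = kmo(R), bartlett = bt)
}

# stats::varimax can stall on a saddle when started from the identity
# (symmetric loading configurations). Run it from several fixed
# orthogonal starts and keep the rotation maximizing the varimax
# criterion.
best_varimax <- function(L, n_starts = 8) {
  k <- ncol(L)
  crit <- function(m) sum(apply(m^2, 2, stats::var))
  best <- NULL
  for (s in seq_len(n_starts)) {
    S0 <- if (s == 1) diag(k) else
      qr.Q(qr(matrix(sin(seq_len(k * k) * s * 2.3) + 0.1, k, k)))
    rot <- stats::varimax(L %*% S0, normalize = TRUE)
    cand <- L %*% S0 %*% rot$rotmat
    if (is.null(best) || crit(cand) > crit(best)) best <- cand
  }
  best
}

#' Measurement uncertainty matrix for PMF
#'
#' EPA species-uncertainty convention: for concentrations above the
#' method detection limit, `u = sqrt((delta * c)^2 + (MDL/3)^2)`;
#' at or below the MDL, `u = 5/6 * MDL`.
#'
#' @param x Concentration matrix (samples x metals, mg/kg).
#' @param mdl Named detection limits (mg/kg), see [detection_limits()].
#' @param delta Relative error fraction in (0, 1]; default 0.1.
#' @return Strictly positive matrix of the same shape as `x`.
#' @export
build_uncertainty <- function(x, mdl = detection_limits(), delta = 0.1) {
  if (delta <= 0 || delta > 1) stop("delta must be in (0, 1]")
  x <- as.matrix(x)
  mdl <- mdl[colnames(x)]
  if (any(is.na(mdl)) || any(mdl <= 0)) {
    stop("detection limits must be positive for every column of x")
  }
  mdl_m <- matrix(mdl, nrow(x), ncol(x), byrow = TRUE)
  u <- sqrt((delta * x)^2 + (mdl_m / 3)^2)
  below <- x <= mdl_m
  u[below] <- 5 / 6 * mdl_m[below]
  dimnames(u) <- dimnames(x)
  u
}

#' Positive matrix factorization with uncertainty weighting
#'
#' Minimizes `Q = sum(((X - G F) / U)^2)` over nonnegative scores `G`
#' (samples x k) and profiles `F` (k x metals) by multiplicative
#' updates on the weighted objective, with multiple random restarts.
#' The scaling ambiguity is resolved by rescaling each factor so its
#' scores average 1, leaving `F` in concentration units. `Q` is
#' nonincreasing within every run; the lowest-Q restart wins (ties by
#' lowest restart index).
#'
#' @param x Nonnegative samples x metals matrix. Zeros are floored at
#'   `mdl/2` when `mdl` is supplied (PMF needs positive weighting).
#' @param u Uncertainty matrix from [build_uncertainty()] (strictly
#'   positive, same shape).
#' @param k Number of factors (default 2); must satisfy
#'   `k < min(dim(x))`.
#' @param n_restarts Random restarts (default 20).
#' @param seed Master seed; restart r uses `seed + r`.
#' @param tol Relative Q change declaring convergence (default 1e-9).
#' @param max_iter Update sweeps per restart (default 5000).
#' @param mdl Optional detection limits used to floor nonpositive
#'   entries at `mdl/2`.
#' @param polish With `k = 2`, resolve the rotational ambiguity of the
#'   two-factor solution by moving to the maximally separated (edge)
#'   representative: exact Q-preserving transformations subtract as
#'   much of each factor from the other as nonnegativity allows, then
#'   the fit is re-polished. Default `TRUE`. See Details.
#' @details A two-factor nonnegative factorization is generally unique
#'   only up to mixing transformations that keep both factors
#'   nonnegative, so `Q` alone cannot pick between a continuum of
#'   near-equivalent solutions. Among these the edge representative —
#'   each profile stripped of the largest feasible multiple of the
#'   other — is the natural reported solution for sparse source
#'   profiles, and is what the contribution percentages refer to.
#' @return A `factor_model`: `G`, `F`, `E`, `Q`, `q_restarts`,
#'   `converged`, `iterations`, `k`.
#' @export
pmf_fit <- function(x, u, k = 2, n_restarts = 20, seed = 1,
                    tol = 1e-9, max_iter = 5000, mdl = NULL,
                    polish = TRUE) {
  x <- as.matrix(x)
  u <- as.matrix(u)
  if (any(x < 0)) stop("PMF requires nonnegative concentrations")
  if (any(u <= 0) || !all(dim(u) == dim(x))) {
    stop("uncertainty matrix must be strictly positive, same shape as x")
  }
  if (k >= min(dim(x))) stop("k must be < min(n_samples, n_metals)")
  if (!is.null(mdl)) {
    mdl_m <- matrix(mdl[colnames(x)], nrow(x), ncol(x), byrow = TRUE)
    zero <- x <= 0
    x[zero] <- mdl_m[zero] / 2
  }

  W <- 1 / u^2
  WX <- W * x
  eps <- .Machine$double.eps
  best <- NULL
  q_restarts <- numeric(n_restarts)
  conv_restarts <- logical(n_restarts)

  for (r in seq_len(n_restarts)) {
    set.seed(as.integer(seed) + r)
    G <- matrix(stats::runif(nrow(x) * k, 0.1, 1), nrow(x), k)
    F <- matrix(stats::runif(k * ncol(x), 0.1, 1), k, ncol(x))
    F <- F * matrix(colMeans(x), k, ncol(x), byrow = TRUE)

    q_prev <- Inf
    q_trace <- numeric(0)
    converged <- FALSE
    n_mu <- if (k == 2) min(10L, max_iter) else max_iter
    for (it in seq_len(max_iter)) {
      if (it <= n_mu) {       # multiplicative warm-up
        GF <- G %*% F
        G <- G * (WX %*% t(F)) / pmax((W * GF) %*% t(F), eps)
        GF <- G %*% F
        F <- F * (t(G) %*% WX) / pmax(t(G) %*% (W * GF), eps)
      } else {                # exact alternating NNLS (k = 2)
        st <- anls2_sweep(x, W, G, F)
        G <- st$G
        F <- st$F
        if (it %% 50 == 0) {  # Q-preserving separation unsticks plateaus
          GF2 <- polish_edge(G, F)
          G <- GF2$G
          F <- GF2$F
        }
      }
      q <- sum(W * (x - G %*% F)^2)
      q_trace <- c(q_trace, q)
      if (it != n_mu &&       # the engine switch may still make progress
          is.finite(q_prev) && abs(q_prev - q) <= tol * max(q_prev, eps)) {
        converged <- TRUE
        q_prev <- q
        break
      }
      q_prev <- q
    }
    q_restarts[r] <- q_prev
    conv_restarts[r] <- converged
    if (is.null(best) || q_prev < best$Q) {
      best <- list(G = G, F = F, Q = q_prev, q_trace = q_trace,
                   restart = r, iterations = length(q_trace),
                   converged = converged)
    }
  }

  polish_trace <- numeric(0)
  if (polish && k == 2) {
    # refine with exact alternating NNLS sweeps, then move to the
    # maximally separated representative; iterate until Q settles
    G <- best$G
    F <- best$F
    q_prev <- best$Q
    for (round in seq_len(20)) {
      for (it in seq_len(50)) {
        st <- anls2_sweep(x, W, G, F)
        G <- st$G
        F <- st$F
      }
      GF2 <- polish_edge(G, F)
      G <- GF2$G
      F <- GF2$F
      q <- sum(W * (x - G %*% F)^2)
      polish_trace <- c(polish_trace, q)
      if (abs(q_prev - q) <= tol * max(q_prev, eps)) break
      q_prev <- q
    }
    best$G <- G
    best$F <- F
    best$Q <- sum(W * (x - G %*% F)^2)
  }

  # fix scaling: per-factor mean score = 1, F carries mg/kg
  s <- colMeans(best$G)
  s[s <= 0] <- 1
  G <- sweep(best$G, 2, s, `/`)
  F <- sweep(best$F, 1, s, `*`)
  dimnames(F) <- list(paste0("factor", seq_len(k)), colnames(x))
  dimnames(G) <- list(rownames(x), paste0("factor", seq_len(k)))
  E <- x - G %*% F

  if (!any(conv_restarts)) {
    warning("no restart converged within max_iter; returning best Q anyway")
  }
  structure(list(G = G, F = F, E = E, Q = best$Q,
                 q_trace = best$q_trace, polish_trace = polish_trace,
                 q_restarts = q_restarts,
                 converged = conv_restarts, best_restart = best$restart,
                 iterations = best$iterations, k = k),
            class = "factor_model")
}

# One sweep of exact alternating nonnegative least squares for k = 2:
# every row of G (then every column of F) is replaced by the exact
# minimizer of the uncertainty-weighted objective with the other block
# fixed — a closed-form 2-variable NNLS, vectorized across rows. Block
# coordinate descent with exact minimization, so Q is nonincreasing.
anls2_sweep <- function(X, W, G, F) {
  G <- nnls2_rows(X, W, F)
  F <- t(nnls2_rows(t(X), t(W), t(G)))
  list(G = G, F = F)
}

# Solve, for every row i: min_{g >= 0} sum_j W[i,j] (X[i,j] - g %*% F[,j])^2
nnls2_rows <- function(X, W, F) {
  f1 <- F[1, ]
  f2 <- F[2, ]
  m11 <- W %*% f1^2
  m22 <- W %*% f2^2
  m12 <- W %*% (f1 * f2)
  v1 <- (W * X) %*% f1
  v2 <- (W * X) %*% f2
  det <- m11 * m22 - m12^2
  det[det <= 0] <- .Machine$double.eps
  g1 <- (m22 * v1 - m12 * v2) / det
  g2 <- (m11 * v2 - m12 * v1) / det
  # where the unconstrained optimum leaves the quadrant, compare the
  # two single-factor boundary solutions
  bad <- which(g1 < 0 | g2 < 0)
  if (length(bad) > 0) {
    c1 <- pmax(v1[bad] / pmax(m11[bad], .Machine$double.eps), 0)
    c2 <- pmax(v2[bad] / pmax(m22[bad], .Machine$double.eps), 0)
    # objective difference up to a constant: -2 v g + g' M g
    q1 <- -2 * v1[bad] * c1 + m11[bad] * c1^2
    q2 <- -2 * v2[bad] * c2 + m22[bad] * c2^2
    use1 <- q1 <= q2
    g1[bad] <- ifelse(use1, c1, 0)
    g2[bad] <- ifelse(use1, 0, c2)
  }
  cbind(as.numeric(g1), as.numeric(g2))
}

# Exact Q-preserving separation for k = 2: repeatedly subtract from
# each profile the largest multiple of the other that keeps it
# nonnegative, compensating in the score matrix (G F is unchanged).
polish_edge <- function(G, F, rounds = 3) {
  for (r in seq_len(rounds)) {
    pos <- F[2, ] > 0
    a <- if (any(pos)) min(F[1, pos] / F[2, pos]) else 0
    if (a > 0) {
      F[1, ] <- pmax(F[1, ] - a * F[2, ], 0)
      G[, 2] <- G[, 2] + a * G[, 1]
    }
    pos <- F[1, ] > 0
    b <- if (any(pos)) min(F[2, pos] / F[1, pos]) else 0
    if (b > 0) {
      F[2, ] <- pmax(F[2, ] - b * F[1, ], 0)
      G[, 1] <- G[, 1] + b * G[, 2]
    }
    if (a == 0 && b == 0) break
  }
  list(G = G, F = F)
}

#' Per-metal source contribution percentages from factor profiles
#'
#' Row-normalizes the profile matrix per metal:
#' `pct[f, m] = F[f, m] / sum_f F[f, m] * 100`.
#'
#' @param f Nonnegative factors x metals profile matrix (or a
#'   `factor_model`, whose `F` is used).
#' @return Factors x metals percentage matrix; columns sum to 100.
#' @export
contribution_percent <- function(f) {
  if (inherits(f, "factor_model")) f <- f$F
  f <- as.matrix(f)
  tot <- colSums(f)
  if (any(tot <= 0)) {
    stop("all-zero profile for metal(s): ",
         paste(colnames(f)[tot <= 0], collapse = ", "))
  }
  sweep(f, 2, tot, `/`) * 100
}

#' Label the two factors as natural vs anthropogenic
#'
#' The factor carrying the larger mean contribution share of Pb and As
#' — the metals that track the geochemical background in this setting —
#' is labelled natural; the other anthropogenic. The labelling score
#' (Pb+As share difference, percentage points) is returned; a gap under
#' 5 points triggers an ambiguity warning.
#'
#' @param model A `factor_model` with `k = 2` (or a 2 x metals profile
#'   matrix).
#' @param tracer_metals Metals anchoring the natural factor; default
#'   `c("Pb", "As")`.
#' @return List: `contributions` (2 x metals percentage matrix with
#'   rows `natural`, `anthropogenic`), `labels` (factor -> label),
#'   `score` (points separating the two factors' tracer shares).
#' @export
assign_factor_labels <- function(model, tracer_metals = c("Pb", "As")) {
  f <- if (inherits(model, "factor_model")) model$F else as.matrix(model)
  if (nrow(f) != 2) stop("factor labelling requires exactly k = 2 factors")
  pct <- contribution_percent(f)
  tracer <- rowMeans(pct[, tracer_metals, drop = FALSE])
  nat <- which.max(tracer)
  score <- abs(diff(tracer))
  if (score < 5) {
    warning("factor labelling ambiguous: tracer shares differ by ",
            round(score, 1), " points")
  }
  labels <- c("anthropogenic", "anthropogenic")
  labels[nat] <- "natural"
  names(labels) <- rownames(pct)
  out <- pct[c(which(labels == "natural"), which(labels == "anthropogenic")), ,
             drop = FALSE]
  rownames(out) <- c("natural", "anthropogenic")
  list(contributions = out, labels = labels, score = unname(score))
}

#' Surface/deep shift in anthropogenic share
#'
#' @param surface,deep Labelled contribution matrices from
#'   [assign_factor_labels()] (rows `natural`, `anthropogenic`).
#' @return Named vector of deep-minus-surface anthropogenic percentage
#'   differences per metal.
#' @export
compare_layers <- function(surface, deep) {
  if (is.list(surface) && !is.null(surface$contributions)) {
    surface <- surface$contributions
  }
  if (is.list(deep) && !is.null(deep$contributions)) {
    deep <- deep$contributions
  }
  if (!identical(colnames(surface), colnames(deep))) {
    stop("mismatched metal sets between layers")
  }
  deep["anthropogenic", ] - surface["anthropogenic", ]
}
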