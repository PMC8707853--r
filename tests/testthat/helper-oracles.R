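# Independent brute-force oracles, written with explicit loops so they do
# not share code paths with the package implementation.

# plain NIPALS PLS1 (no residual standardization)
nipalsPls1Oracle <- function(X, y, nf) {
    n <- nrow(X); p <- ncol(X)
    xc <- numeric(p)
    for (j in seq_len(p)) xc[j] <- mean(X[, j])
    yc <- mean(y)
    E <- X
    for (j in seq_len(p)) E[, j] <- X[, j] - xc[j]
    f <- y - yc
    W <- P <- matrix(0, p, nf)
    q <- numeric(nf)
    for (a in seq_len(nf)) {
        w <- numeric(p)
        for (j in seq_len(p)) w[j] <- sum(E[, j] * f)
        w <- w / sqrt(sum(w * w))
        tt <- numeric(n)
        for (i in seq_len(n)) tt[i] <- sum(E[i, ] * w)
        t2 <- sum(tt * tt)
        pv <- numeric(p)
        for (j in seq_len(p)) pv[j] <- sum(E[, j] * tt) / t2
        qa <- sum(f * tt) / t2
        for (i in seq_len(n)) for (j in seq_len(p))
            E[i, j] <- E[i, j] - tt[i] * pv[j]
        f <- f - qa * tt
        W[, a] <- w; P[, a] <- pv; q[a] <- qa
    }
    list(xc = xc, yc = yc, W = W, P = P, q = q)
}

nipalsPredictOracle <- function(m, Xnew, k) {
    n <- nrow(Xnew)
    yhat <- rep(m$yc, n)
    E <- Xnew
    for (j in seq_len(ncol(Xnew))) E[, j] <- Xnew[, j] - m$xc[j]
    for (a in seq_len(k)) {
        tt <- numeric(n)
        for (i in seq_len(n)) tt[i] <- sum(E[i, ] * m$W[, a])
        yhat <- yhat + m$q[a] * tt
        for (i in seq_len(n)) for (j in seq_len(ncol(Xnew)))
            E[i, j] <- E[i, j] - tt[i] * m$P[j, a]
    }
    yhat
}

# literal step-by-step math-treatment code oracle for one spectrum
mathCodeOracle <- function(x, wl, d, g, s1, s2) {
    smooth <- function(v, w, s) {
        if (s <= 1) return(list(v = v, w = w))
        nv <- length(v) - s + 1
        out <- numeric(nv); ow <- numeric(nv)
        for (i in seq_len(nv)) {
            out[i] <- mean(v[i:(i + s - 1)])
            ow[i] <- mean(w[i:(i + s - 1)])
        }
        list(v = out, w = ow)
    }
    gapDeriv <- function(v, w, g) {
        nv <- length(v) - g
        out <- numeric(nv); ow <- numeric(nv)
        for (i in seq_len(nv)) {
            out[i] <- v[i + g] - v[i]
            ow[i] <- (w[i + g] + w[i]) / 2
        }
        list(v = out, w = ow)
    }
    cur <- smooth(x, wl, s1)
    if (d >= 1) for (k in seq_len(d)) cur <- gapDeriv(cur$v, cur$w, g)
    smooth(cur$v, cur$w, s2)
}

# truncated-normal moments by numerical integration
truncMomentsOracle <- function(mu, sigma, lo, hi) {
    z <- stats::integrate(function(x) stats::dnorm(x, mu, sigma),
                          lo, hi)$value
    m <- stats::integrate(function(x) x * stats::dnorm(x, mu, sigma),
                          lo, hi)$value / z
    v <- stats::integrate(function(x) (x - m)^2 * stats::dnorm(x, mu, sigma),
                          lo, hi)$value / z
    c(mean = m, sd = sqrt(v))
}

# squared Mahalanobis distance from first principles
mahalanobisOracle <- function(S) {
    ctr <- colMeans(S)
    cvi <- solve(cov(S))
    apply(S, 1, function(s) drop(t(s - ctr) %*% cvi %*% (s - ctr)))
}

# Kruskal-Wallis H for tie-free data
kruskalOracle <- function(values, groups) {
    r <- rank(values)
    N <- length(values)
    parts <- split(r, groups)
    12 / (N * (N + 1)) *
        sum(vapply(parts, function(ri)
            length(ri) * (mean(ri) - (N + 1) / 2)^2, numeric(1)))
}
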