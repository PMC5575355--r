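#' @include updates.R
NULL

# --- Segment refinement of the joint (X, P) arrangement -------------------
#
# The row-assignment step relocates samples one at a time, so a group split
# into two contiguous runs separated by other blocks is a local minimum of
# the alternating scheme: merging the runs would require transporting a
# whole segment across the arrangement. These moves do exactly that: a
# contiguous segment of X rows is relocated (optionally reversed) together
# with its assigned samples, which leaves the fidelity term untouched and
# changes only the adjacency structure at the three cut edges.
#
# Moves are scored on the arrangement of the *assigned observed rows*
# (the sequence t(P) B), not on the current X: after a move the X-step
# re-converges towards the TV-denoising of t(P) B, so the observed-row
# adjacency predicts where the energy will settle, whereas the current X
# has already been smoothed into its surroundings and hides a stranded
# segment. Moves are therefore speculative with respect to the
# instantaneous energy; the solver's incumbent bookkeeping keeps only
# genuinely better iterates.

.adjDist <- function(X, boundary) {
    m <- nrow(X)
    nxt <- if (boundary == "circular") c(2:m, 1L) else 2:m
    rowSums(abs(X[seq_along(nxt), , drop = FALSE] -
                X[nxt, , drop = FALSE]))
}

# l1 distance lookup; NA index marks a missing edge on the open line
.edist <- function(D1, u, v) {
    if (is.na(u) || is.na(v)) return(0)
    D1[u, v]
}

# Block boundaries: edges whose adjacent-row distance stands out against
# the within-block level. d[i] is the edge between positions i and i+1
# (wrapping for circular).
.findCuts <- function(d) {
    thr <- max(2 * stats::median(d), 1e-12)
    cuts <- which(d > thr)
    if (length(cuts) > 24L)
        cuts <- sort(cuts[order(d[cuts], decreasing = TRUE)[1:24]])
    cuts
}

# Best strictly improving segment relocation. Positions are linear 1..m;
# for the circular boundary the caller has rotated the arrangement so that
# the wrap edge is the largest gap, and modular edges (m,1) enter the
# deltas. Returns NULL when nothing improves.
.bestSegmentMove <- function(D1, cuts, boundary, scale = 1) {
    m <- nrow(D1)
    circular <- boundary == "circular"
    bnds <- sort(unique(c(0L, cuts, m)))
    if (length(bnds) < 4L) return(NULL)   # fewer than 3 blocks
    starts <- utils::head(bnds, -1L) + 1L
    ends <- bnds[-1L]
    k <- length(starts)
    pa <- function(p) if (p > 1L) p - 1L else if (circular) m else NA_integer_
    nb <- function(p) if (p < m) p + 1L else if (circular) 1L else NA_integer_
    gaps <- if (circular) ends else bnds   # gap g = insert after position g
    best <- NULL
    bestDelta <- -1e-9 * max(1, scale)
    for (s in seq_len(k)) {
        a <- starts[s]; b <- ends[s]
        if (b - a + 1L >= m - 1L) next
        paa <- pa(a); nbb <- nb(b)
        removed <- .edist(D1, paa, a) + .edist(D1, b, nbb) -
                   .edist(D1, paa, nbb)
        for (g in gaps) {
            if (g >= a - 1L && g <= b) next     # inside or no-op
            gn <- if (g == 0L) 1L else nb(g)
            gq <- if (g == 0L) NA_integer_ else g
            if (!is.na(gn) && gn >= a && gn <= b) next
            base <- .edist(D1, gq, gn)
            for (rev in c(FALSE, TRUE)) {
                h1 <- if (rev) b else a
                h2 <- if (rev) a else b
                delta <- .edist(D1, gq, h1) + .edist(D1, h2, gn) - base -
                         removed
                if (delta < bestDelta) {
                    bestDelta <- delta
                    best <- list(a = a, b = b, g = g, rev = rev,
                                 delta = delta)
                }
            }
        }
    }
    best
}

# New arrangement as a vector of old positions: segment [a..b] (optionally
# reversed) reinserted after gap position g (0 = front).
.moveRho <- function(m, a, b, g, rev) {
    seg <- a:b
    if (rev) seg <- rev(seg)
    rest <- setdiff(seq_len(m), a:b)
    at <- if (g == 0L) 0L else match(g, rest)
    append(rest, seg, after = at)
}

.applyRho <- function(env, rho) {
    npos <- integer(length(rho))
    npos[rho] <- seq_along(rho)
    env$X <- env$X[rho, , drop = FALSE]
    env$Y <- env$Y[rho, , drop = FALSE]
    env$dual <- env$dual[rho, , drop = FALSE]
    env$ord <- npos[env$ord]
    invisible(env)
}

# Canonical linear reading of a circular arrangement: rotate so that the
# largest adjacent gap of the assigned observed rows sits between the last
# and the first position.
.canonicalRotation <- function(env, Bv) {
    d <- .adjDist(Bv[order(env$ord), , drop = FALSE], "circular")
    if (max(d) <= 1e-12) return(invisible(env))  # no gap to cut at
    cut <- which.max(d)
    m <- nrow(env$X)
    if (cut != m)
        .applyRho(env, c((cut + 1L):m, seq_len(cut)))
    invisible(env)
}

# Iterated segment refinement; mutates the environment holding X, Y, dual,
# ord. Returns the number of moves applied.
.refineSegments <- function(env, Bv, boundary, maxMoves = 12L) {
    if (boundary == "circular") .canonicalRotation(env, Bv)
    moves <- 0L
    # adjacency of the observed rows in their assigned arrangement
    D1 <- as.matrix(stats::dist(Bv[order(env$ord), , drop = FALSE],
                                method = "manhattan"))
    while (moves < maxMoves) {
        m <- nrow(env$X)
        d <- if (boundary == "circular")
            D1[cbind(seq_len(m), c(2:m, 1L))]
        else
            D1[cbind(seq_len(m - 1L), 2:m)]
        mv <- .bestSegmentMove(D1, .findCuts(d), boundary, scale = sum(d))
        if (is.null(mv)) break
        rho <- .moveRho(m, mv$a, mv$b, mv$g, mv$rev)
        .applyRho(env, rho)
        D1 <- D1[rho, rho]
        moves <- moves + 1L
    }
    moves
}
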