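# Each alternating step must attain the exact minimum of its subproblem;
# every step is checked against an independent oracle.

test_that("X-step: gamma -> 0 limit returns t(P) B", {
    set.seed(21)
    B <- matrix(rnorm(20), 5, 4)
    D <- buildDifferenceOperator(5, "circular")
    ord <- SampleOrdering(c(2L, 5L, 1L, 4L, 3L))
    X <- updateX(ord, B, matrix(0, 5, 4), matrix(0, 5, 4), gamma = 0, D)
    expect_equal(X, B[order(orderIndices(ord)), ], tolerance = 1e-10)
})

test_that("X-step: FFT path equals the dense solve and is stationary", {
    set.seed(22)
    m <- 6L; n <- 4L
    B <- matrix(rnorm(m * n), m, n)
    Y <- matrix(rnorm(m * n), m, n)
    lam <- matrix(rnorm(m * n), m, n)
    gamma <- 1.3
    D <- buildDifferenceOperator(m, "circular")
    ord <- SampleOrdering(sample.int(m))
    X <- updateX(ord, B, Y, lam, gamma, D)

    Dd <- D@matrixForm
    rhs <- 2 * B[order(orderIndices(ord)), ] - crossprod(Dd, lam) +
        gamma * crossprod(Dd, Y)
    Xdense <- solve(2 * diag(m) + gamma * crossprod(Dd), rhs)
    expect_lt(max(abs(X - Xdense)), 1e-8)
    # stationarity of the quadratic subproblem
    resid <- (2 * diag(m) + gamma * crossprod(Dd)) %*% X - rhs
    expect_lt(max(abs(resid)), 1e-8)
})

test_that("X-step: FFT/dense agreement holds across sizes", {
    set.seed(23)
    for (m in c(2L, 3L, 7L, 16L, 32L)) {
        D <- buildDifferenceOperator(m, "circular")
        B <- matrix(rnorm(m * 3L), m, 3L)
        Y <- matrix(rnorm(m * 3L), m, 3L)
        lam <- matrix(rnorm(m * 3L), m, 3L)
        X <- updateX(SampleOrdering(seq_len(m)), B, Y, lam, 0.8, D)
        Dd <- D@matrixForm
        rhs <- 2 * B - crossprod(Dd, lam) + 0.8 * crossprod(Dd, Y)
        Xd <- solve(2 * diag(m) + 0.8 * crossprod(Dd), rhs)
        expect_lt(max(abs(X - Xd)), 1e-8)
    }
})

test_that("Y-step: soft thresholding solves the scalar prox problem", {
    set.seed(24)
    X <- matrix(rnorm(6), 3, 2)
    lam <- matrix(rnorm(6), 3, 2)
    alpha <- 0.7; gamma <- 2.1
    D <- buildDifferenceOperator(3, "circular")
    Y <- updateY(X, lam, alpha, gamma, D)
    C <- D@matrixForm %*% X + lam / gamma
    for (i in seq_along(C)) {
        grid <- seq(C[i] - 2, C[i] + 2, by = 1e-4)
        vals <- alpha * abs(grid) + (gamma / 2) * (grid - C[i])^2
        expect_equal(Y[i], grid[which.min(vals)], tolerance = 1e-3)
    }
    # alpha = 0 is the identity on D X + lambda / gamma
    expect_equal(updateY(X, lam, 0, gamma, D), C)
    # constant columns with zero dual fall in the dead zone (open boundary)
    Do <- buildDifferenceOperator(3, "open")
    Xc <- matrix(rep(c(1, -2), each = 3), 3, 2)
    expect_equal(updateY(Xc, matrix(0, 3, 2), 0.5, 1, Do),
                 matrix(0, 3, 2))
    expect_error(updateY(X, lam, 0.5, 0, D), "gamma")
})

test_that("P-step: matches exhaustive enumeration and resolves ties", {
    # rows must exchange
    B <- rbind(c(1, 0), c(0, 1))
    X <- rbind(c(0, 1), c(1, 0))
    expect_equal(orderIndices(updateP(X, B)), c(2L, 1L))
    # zero-cost diagonal prefers identity
    set.seed(25)
    B5 <- matrix(rnorm(15), 5, 3)
    expect_equal(orderIndices(updateP(B5, B5)), 1:5)
    # full enumeration oracle at m = 5 (120 permutations)
    for (rep in 1:5) {
        X5 <- matrix(rnorm(15), 5, 3)
        C5 <- matrix(rnorm(15), 5, 3)
        ord <- orderIndices(updateP(X5, C5))
        costs <- vapply(allPermutations(5L),
                        function(p) sum((X5[p, ] - C5)^2), numeric(1))
        expect_equal(sum((X5[ord, ] - C5)^2), min(costs),
                     tolerance = 1e-10)
    }
    expect_error(updateP(matrix(0, 2, 2), matrix(0, 3, 2)), "shape")
})

test_that("P-step optimality also holds at m = 6", {
    set.seed(26)
    X <- matrix(rnorm(24), 6, 4)
    B <- matrix(rnorm(24), 6, 4)
    ord <- orderIndices(updateP(X, B))
    costs <- vapply(allPermutations(6L),
                    function(p) sum((X[p, ] - B)^2), numeric(1))
    expect_equal(sum((X[ord, ] - B)^2), min(costs), tolerance = 1e-10)
})

test_that("dual ascent accumulates the constraint violation linearly", {
    set.seed(27)
    X <- matrix(rnorm(8), 4, 2)
    D <- buildDifferenceOperator(4, "circular")
    DX <- D@matrixForm %*% X
    Y <- matrix(rnorm(8), 4, 2)
    expect_equal(updateDual(matrix(1, 4, 2), X, DX, 2.5, D),
                 matrix(1, 4, 2))
    expect_equal(updateDual(matrix(0, 4, 2), X, Y, 1, D), DX - Y)
    once <- updateDual(matrix(0, 4, 2), X, Y, 0.5, D)
    twice <- updateDual(once, X, Y, 0.5, D)
    expect_equal(twice, 2 * 0.5 * (DX - Y))
})
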