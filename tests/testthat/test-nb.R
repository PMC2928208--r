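test_that("nbLogPmf matches closed forms and dnbinom", {
    # u = 0: pmf = (1/(1+l*mu*phi))^(1/phi)
    expect_equal(nbLogPmf(0, 1, 1, 1), log(1 / 2))
    # phi = 1, l*mu = 1 reduces to geometric with success prob 1/2
    expect_equal(nbLogPmf(3, 1, 1, 1), log(2^-4))
    # general case against R's own NB pmf (size = 1/phi, mu = l*mu)
    cases <- expand.grid(u = c(0, 1, 5, 17, 300), l = c(0.5, 1, 2, 9e4),
                         mu = c(1e-4, 0.7, 1.3), phi = c(0.05, 0.4, 2))
    got <- with(cases, nbLogPmf(u, l, mu, phi))
    want <- with(cases, dnbinom(u, size = 1 / phi, mu = l * mu, log = TRUE))
    expect_equal(got, want, tolerance = 1e-12)
    # recurrence oracle: P(u)/P(u-1) = (u - 1 + 1/phi) / u * lmu*phi/(1+lmu*phi)
    l <- 2; mu <- 1.3; phi <- 0.4; lm <- l * mu
    lp <- nbLogPmf(0:5, l, mu, phi)
    for (u in 1:5)
        expect_equal(lp[u + 1] - lp[u],
                     log((u - 1 + 1 / phi) / u * lm * phi / (1 + lm * phi)))
})

test_that("nbLogPmf normalizes and approaches the Poisson limit", {
    for (p in list(c(1, 1, 1), c(2, 1.3, 0.4), c(9e4, 3e-4, 2))) {
        u <- 0:5000
        expect_equal(sum(exp(nbLogPmf(u, p[1], p[2], p[3]))), 1,
                     tolerance = 1e-8)
    }
    # the NB-Poisson log-pmf gap is O(phi): ~phi*((u - l*mu)^2 - u)/2, so
    # it shrinks linearly and is below 1e-6 by phi = 1e-10
    u <- 0:50
    gap8 <- max(abs(nbLogPmf(u, 1.7, 2.2, 1e-8) -
                    dpois(u, 1.7 * 2.2, log = TRUE)))
    gap10 <- max(abs(nbLogPmf(u, 1.7, 2.2, 1e-10) -
                     dpois(u, 1.7 * 2.2, log = TRUE)))
    expect_lt(gap8, 2e-5)
    expect_lt(gap10, 1e-6)
    expect_equal(gap10 / gap8, 0.01, tolerance = 0.05)
    # phi = 0 is evaluated exactly as Poisson
    expect_equal(nbLogPmf(u, 1.7, 2.2, 0), dpois(u, 1.7 * 2.2, log = TRUE))
})

test_that("nbLogPmf rejects invalid arguments", {
    expect_error(nbLogPmf(-1, 1, 1, 1), "integer")
    expect_error(nbLogPmf(1, 0, 1, 1), "libSize")
    expect_error(nbLogPmf(1, 1, 1, -0.1), "phi")
})

makePrior <- function(model, mu, phi) {
    methods::new("PriorSample", model = model,
                 mu = as.matrix(mu), phi = as.matrix(phi),
                 provenance = seq_len(nrow(as.matrix(mu))))
}

test_that("marginalLikelihood with a single prior draw is the plain log-lik", {
    cd <- makeCountData(matrix(c(3L, 7L, 2L, 9L), 1, 4),
                        conditions = c("A", "A", "B", "B"),
                        libSizes = c(1, 2, 1, 3))
    model <- validateModel(ModelDefinition(list(1:2, 3:4)), 4)
    pri <- makePrior(model, mu = cbind(1.2, 0.8), phi = cbind(0.3, 0.3))
    got <- marginalLikelihood(cd, model, pri)
    want <- sum(nbLogPmf(c(3, 7), c(1, 2), 1.2, 0.3)) +
        sum(nbLogPmf(c(2, 9), c(1, 3), 0.8, 0.3))
    expect_equal(unname(got), want)
})

test_that("marginalLikelihood of an all-zero tuple matches direct arithmetic", {
    cd <- makeCountData(matrix(0L, 1, 3), conditions = rep("A", 3),
                        libSizes = c(1, 2, 3))
    model <- validateModel(ModelDefinition(list(1:3)), 3)
    mu <- c(0.5, 1.5, 2.5); phi <- c(0.2, 1, 3)
    pri <- makePrior(model, mu = cbind(mu), phi = cbind(phi))
    want <- log(mean(sapply(1:3, function(s)
        prod((1 / (1 + c(1, 2, 3) * mu[s] * phi[s]))^(1 / phi[s])))))
    expect_equal(unname(marginalLikelihood(cd, model, pri)), want)
})

test_that("marginalLikelihood equals a naive double-loop oracle", {
    set.seed(42)
    grid <- expand.grid(mu = seq(0.2, 3, length.out = 10),
                        phi = seq(0.05, 1, length.out = 5))
    draws <- grid[sample(nrow(grid), 50, replace = TRUE), ]
    cd <- makeCountData(matrix(c(4L, 9L), 1, 2), conditions = c("A", "A"),
                        libSizes = c(1.5, 2.5))
    model <- validateModel(ModelDefinition(list(1:2)), 2)
    pri <- makePrior(model, mu = cbind(draws$mu), phi = cbind(draws$phi))
    naive <- mean(sapply(seq_len(50), function(s)
        dnbinom(4, size = 1 / draws$phi[s], mu = 1.5 * draws$mu[s]) *
        dnbinom(9, size = 1 / draws$phi[s], mu = 2.5 * draws$mu[s])))
    expect_equal(unname(marginalLikelihood(cd, model, pri)), log(naive),
                 tolerance = 1e-10)
})

test_that("marginalLikelihood is invariant under within-set and prior order", {
    set.seed(7)
    cts <- matrix(rpois(8, 6), 2, 4)
    cd <- makeCountData(cts, conditions = c("A", "A", "A", "A"),
                        libSizes = c(1, 1, 2, 2))
    model <- validateModel(ModelDefinition(list(1:4)), 4)
    mu <- runif(20, 0.5, 5); phi <- runif(20, 0.01, 1)
    pri <- makePrior(model, cbind(mu), cbind(phi))
    base <- marginalLikelihood(cd, model, pri)
    # permute samples within the set (swap the two columns with equal l)
    cd2 <- makeCountData(cts[, c(2, 1, 4, 3)], conditions = rep("A", 4),
                         libSizes = c(1, 1, 2, 2))
    expect_equal(unname(marginalLikelihood(cd2, model, pri)), unname(base))
    # permute prior draws
    p <- sample(20)
    pri2 <- makePrior(model, cbind(mu[p]), cbind(phi[p]))
    expect_equal(marginalLikelihood(cd, model, pri2), base)
})

test_that("Monte-Carlo marginal converges to the discrete-prior expectation", {
    # prior supported on a fixed 2-parameter grid: the exact value is the
    # weighted enumeration; i.i.d. draws from the grid must converge to it
    grid <- expand.grid(mu = exp(seq(log(0.05), log(8), length.out = 40)),
                        phi = seq(0.01, 1.5, length.out = 25))
    u <- c(3L, 11L); l <- c(1.2, 2.1)
    exact <- log(mean(dnbinom(u[1], size = 1 / grid$phi, mu = l[1] * grid$mu) *
                      dnbinom(u[2], size = 1 / grid$phi, mu = l[2] * grid$mu)))
    cd <- makeCountData(matrix(u, 1, 2), conditions = c("A", "A"),
                        libSizes = l)
    model <- validateModel(ModelDefinition(list(1:2)), 2)
    set.seed(11)
    err <- sapply(c(100, 10000), function(S) {
        ix <- sample(nrow(grid), S, replace = TRUE)
        pri <- makePrior(model, cbind(grid$mu[ix]), cbind(grid$phi[ix]))
        abs(exp(unname(marginalLikelihood(cd, model, pri))) - exp(exact)) /
            exp(exact)
    })
    expect_lt(err[2], err[1])          # error shrinks with |Theta|
    expect_lt(err[2], 0.05)
})

test_that("marginalLikelihood rejects priors built for another model", {
    cd <- makeCountData(matrix(1L, 1, 4), conditions = c("A", "A", "B", "B"))
    m1 <- validateModel(ModelDefinition(list(1:2, 3:4)), 4)
    m2 <- validateModel(ModelDefinition(list(1:4)), 4)
    pri <- makePrior(m1, cbind(1, 1), cbind(0.1, 0.1))
    expect_error(marginalLikelihood(cd, m2, pri), "built for model")
})
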