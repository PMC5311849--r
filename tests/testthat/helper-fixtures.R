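# Shared fixtures: tiny files written on the fly and an independent
# brute-force weighted least-squares oracle.

writeTempLines <- function(lines, ext = "") {
    path <- tempfile(fileext = ext)
    writeLines(lines, path)
    path
}

# A well-formed 3-individual sample file with one continuous phenotype,
# one binary phenotype and a missing value.
sampleFixture <- function() {
    writeTempLines(c(
        "ID_1 ID_2 missing pheno_a pheno_b",
        "0 0 0 P B",
        "ind1 ind1 0 1.5 0",
        "ind2 ind2 0 -0.3 1",
        "ind3 ind3 0 NA 1"))
}

# Build a GenotypeProbs from a list of per-variant triplet matrices
# (individuals x 3).
genoFromTriplets <- function(tripletsByVariant, positions = NULL) {
    V <- length(tripletsByVariant)
    mats <- lapply(1:3, function(k)
        do.call(rbind, lapply(tripletsByVariant, function(m) m[, k])))
    if (is.null(positions)) positions <- 100L * seq_len(V)
    GenotypeProbs(mats[[1]], mats[[2]], mats[[3]],
                  snpID = paste0("snp", seq_len(V)),
                  rsID = paste0("rs", seq_len(V)),
                  position = positions,
                  alleleA = rep("A", V), alleleB = rep("G", V))
}

# Independent oracle: weighted normal equations with explicit dense
# diagonal weight matrix, likelihood recomputed from its closed form.
bruteWLS <- function(z, Y, w) {
    X <- cbind(1, Y)
    W <- diag(w, nrow = length(z))
    beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% z)
    e <- as.numeric(z - X %*% beta)
    N <- length(z)
    wrss <- as.numeric(t(e) %*% W %*% e)
    sigma2 <- wrss / N
    loglik <- 0.5 * sum(log(w)) - (N / 2) * (log(2 * pi * sigma2) + 1)
    ses <- sqrt(diag(solve(t(X) %*% W %*% X)) * wrss / (N - ncol(X)))
    list(coef = as.numeric(beta), ses = as.numeric(ses),
         sigma2 = sigma2, loglik = loglik)
}

randomWLSInstance <- function(maxN = 50L, maxK = 3L) {
    N <- sample(8:maxN, 1)
    K <- sample(seq_len(maxK), 1)
    list(z = runif(N), Y = matrix(rnorm(N * K), N, K),
         w = sample(1:30, N, replace = TRUE))
}
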