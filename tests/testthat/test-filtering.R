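test_that("subscores sum the configured items and derive percent change", {
    pre <- data.frame(item20 = 2, item21 = 1,
                      item22_neck = 2, item22_ra = 2, item22_la = 1,
                      item22_rl = 1, item22_ll = 2,
                      item23_r = 2, item23_l = 2, item24_r = 2, item24_l = 2,
                      item25_r = 2, item25_l = 2, item26_r = 2, item26_l = 2,
                      item18 = 1, item19 = 1, item27 = 1, item28 = 1,
                      item29 = 2, item30 = 2)
    post <- pre
    post[, grep("item2[3-6]", names(post))] <- 1      # bradykinesia halves
    post[, grep("item22", names(post))] <- c(1, 1, 0, 1, 1)
    s <- computeSubscores(pre, post)
    expect_equal(s$baseline_bradykinesia, 16)
    expect_equal(s$improvement_bradykinesia, 50)      # 16 -> 8
    expect_equal(s$baseline_rigidity, 8)              # [2,2,1,1,2]
    expect_equal(s$improvement_rigidity, 50)          # 8 -> 4
    expect_equal(s$baseline_gait, 4)
    expect_equal(s$baseline_axial_nogait, 4)
    # unchanged scores give 0 % for every symptom
    s0 <- computeSubscores(pre, pre)
    expect_true(all(s0[, grep("improvement_", names(s0))] == 0))
    # zero baseline leaves improvement undefined, never zero
    pre0 <- pre; pre0$item20 <- 0; pre0$item21 <- 0
    post0 <- pre0
    expect_true(is.na(computeSubscores(pre0, post0)$improvement_tremor))
    # a missing item propagates to a missing subscore
    preNA <- pre; preNA$item23_r <- NA
    expect_true(is.na(computeSubscores(preNA, post)$baseline_bradykinesia))
})

test_that("tremor exclusions drop low-baseline and 100%-improved patients", {
    tab <- data.frame(baseline_tremor = c(1, 4, 2, 5, NA),
                      improvement_tremor = c(50, 100, 60, 20, 10),
                      baseline_axial = c(3, 3, 3, 0, 3),
                      improvement_axial = c(10, 20, 30, NA, 50))
    expect_equal(applyExclusions(tab, "tremor"),
                 c(FALSE, FALSE, TRUE, TRUE, FALSE))
    expect_equal(applyExclusions(tab, "axial"),
                 c(TRUE, TRUE, TRUE, FALSE, TRUE))
})

test_that("screening applies strict thresholds over all fields", {
    cfg <- screeningConfig()
    # 2 of 100 fields above 1.5 V/mm (2 % > 0.5 %) -> screened
    P1 <- rbind(c(rep(2, 2), rep(0.1, 98)),
                c(rep(2, 1), rep(0.1, 199))[1:100],   # exactly 1 of 100 = 1 %
                rep(0.1, 100))
    scr <- fibertune:::.screenPeaks(P1, cfg)
    expect_equal(scr, c(TRUE, TRUE, FALSE))
    # exactly 0.5 % is NOT screened (strict >)
    P2 <- matrix(0.1, 2, 200)
    P2[1, 1] <- 2
    expect_equal(fibertune:::.screenPeaks(P2, cfg), c(FALSE, FALSE))
    expect_equal(fibertune:::.screenPeaks(P2,
                     screeningConfig(minFieldFraction = 0.004)),
                 c(TRUE, FALSE))
    # raising the intensity threshold never adds streamlines
    set.seed(3)
    P <- matrix(rexp(500, 1), 50, 10)
    for (thr in c(0.5, 1, 1.5, 2, 4)) {
        lo <- fibertune:::.screenPeaks(P, screeningConfig(eThreshold = thr))
        hi <- fibertune:::.screenPeaks(P, screeningConfig(eThreshold = thr + 1))
        expect_true(all(lo | !hi))
    }
})

test_that("Spearman correlation matches the rank formula and exact null", {
    r <- spearmanCorrelate(c(0.1, 0.2, 0.3, 0.4), c(10, 30, 20, 40))
    expect_equal(r$rho, 0.8)                 # 1 - 6*1/(4*15) hand formula
    expect_equal(r$p, 1 / 3, tolerance = 1e-12)   # 2 * (4/24) enumerated
    expect_equal(spearmanCorrelate(1:6, (1:6)^3)$rho, 1)
    expect_true(spearmanCorrelate(c(1, 1, 1, 1), 1:4)$degenerate)
    expect_error(spearmanCorrelate(1:3, 3:1), ">= 4")
    # exact p equals an independently coded exhaustive enumeration (n <= 6)
    enumP <- function(x, y) {
        perms <- as.matrix(expand.grid(rep(list(seq_along(y)),
                                           length(y))))
        perms <- perms[apply(perms, 1, function(r)
            length(unique(r)) == length(y)), , drop = FALSE]
        obs <- cor(x, y, method = "spearman")
        rhos <- apply(perms, 1, function(idx)
            cor(x, y[idx], method = "spearman"))
        mean(abs(rhos) >= abs(obs) - 1e-12)
    }
    set.seed(5)
    for (i in 1:8) {
        n <- sample(4:6, 1)
        x <- rnorm(n)
        y <- sample(n)                  # ties-free draws
        got <- spearmanCorrelate(x, y)
        expect_equal(got$rho, cor(x, y, method = "spearman"))
        expect_equal(got$p, enumP(x, y), tolerance = 1e-12)
    }
    # t-approximation path agrees with cor.test for larger n
    set.seed(6)
    x <- rnorm(30); y <- x + rnorm(30)
    ct <- cor.test(x, y, method = "spearman")
    got <- spearmanCorrelate(x, y)
    expect_equal(got$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p, ct$p.value, tolerance = 0.02)
})

test_that("FDR correction matches a brute-force Benjamini-Hochberg", {
    r <- fdrCorrect(c(0.01, 0.02, 0.04, 0.5))
    expect_equal(r$reject, c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(r$q, c(0.04, 0.04, 0.04 * 4 / 3, 0.5), tolerance = 1e-12)
    expect_equal(fdrCorrect(rep(1, 5))$reject, rep(FALSE, 5))
    expect_true(fdrCorrect(0.04)$reject)     # q = p when m = 1
    bruteBH <- function(p) {
        m <- length(p)
        o <- order(p)
        q <- rep(NA_real_, m)
        prev <- 1
        for (k in m:1) {
            prev <- min(prev, m * p[o[k]] / k)
            q[o[k]] <- prev
        }
        q
    }
    set.seed(9)
    for (i in 1:1000) {
        p <- runif(sample(1:40, 1))^sample(1:3, 1)
        r <- fdrCorrect(p)
        expect_equal(r$q, bruteBH(p), tolerance = 1e-12)
        expect_true(all(r$q >= p - 1e-15))
    }
})

test_that("top-fiber selection respects quotas, signs and stable ties", {
    tiny <- tinyStudy()
    sel <- selectTopFibers(tiny$model, "bradykinesia", nPos = 20, nNeg = 10)
    st <- streamlineStats(tiny$model, "bradykinesia")
    expect_length(sel$positive, 20L)
    expect_true(all(st$rho[sel$positive] > 0))
    expect_true(all(st$screened[sel$positive]))
    expect_equal(sel$positive,
                 sel$positive[order(-st$rho[sel$positive], sel$positive)])
    # fewer available than the quota -> take all
    sel2 <- selectTopFibers(tiny$model, "bradykinesia", nPos = 10^6,
                            nNeg = 10^6)
    expect_lte(length(sel2$positive), nStreamlines(tiny$atlas))
    # ties at the cutoff break by streamline index
    st2 <- data.frame(rho = c(0.5, 0.5, 0.5, -0.2), p = 0.001, q = 0.001,
                      screened = TRUE, selected = FALSE, sign = c(1, 1, 1, -1))
    picked <- fibertune:::.selectFromStats(st2$rho, st2$screened, st2$q,
                                           selectionConfig(nPos = 2, nNeg = 5))
    expect_equal(picked$positive, c(1L, 2L))
})

test_that("the model build is deterministic and tags the generating bundles", {
    tiny <- tinyStudy()
    m2 <- suppressWarnings(buildTractModel(tiny$cohort, tiny$atlas,
                                           peaks = tiny$peaks))
    expect_identical(tiny$model@stats, m2@stats)
    lab <- bundleLabels(tiny$atlas)
    for (sym in symptomNames(tiny$cohort)) {
        st <- streamlineStats(tiny$model, sym)
        top <- order(-st$rho)[1:20]
        # the strongest positive fibers are enriched for the true bundle
        # (bundle base rate is 0.2)
        expect_gte(mean(lab[top] == sym), 0.35)
    }
})

test_that("Welch filtering handles activation fractions and group sizes", {
    act <- rbind(c(1, 1, 0, 0), c(1, 0, 0, 0), c(0, 0, 0, 0))
    imp <- c(60, 62, 40, 38)
    r <- ttestFilter(act, imp, minActivationFraction = 0.05)
    # activated {60, 62} vs {40, 38}: Welch t = 22 / sqrt(2/2 + 2/2)
    expect_equal(r$t[1], 22 / sqrt(2), tolerance = 1e-9)
    expect_true(is.na(r$t[2]))               # one-member group skipped
    expect_true(is.na(r$t[3]))               # never activated
    act2 <- rbind(c(1, rep(0, 24)))          # 4 % < 5 % -> excluded
    expect_true(is.na(ttestFilter(act2, rnorm(25))$t[1]))
    r3 <- ttestFilter(rbind(c(1, 1, 0, 0)), c(5, 7, 5, 7))
    expect_equal(r3$t[1], 0)                 # identical group means
})

test_that("residualization matches hand-computed least squares", {
    x <- c(1, 2, 3, 4)
    y <- c(2.0, 2.5, 4.5, 5.0)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    intercept <- mean(y) - slope * mean(x)
    expect_equal(residualize(y, x), y - intercept - slope * x,
                 tolerance = 1e-12)
    expect_equal(residualize(x, x), rep(0, 4), tolerance = 1e-12)
    expect_equal(mean(residualize(y, x)), 0, tolerance = 1e-12)
    expect_error(residualize(y, rep(1, 4)), "zero variance")
})

test_that("correlation power follows the Fisher-z closed form", {
    expect_gte(powerCorrelation(129, 0.27), 0.87)
    expect_equal(powerCorrelation(129, 0.27), 0.8745, tolerance = 1e-3)
    expect_equal(powerCorrelation(129, 1e-9), 0.05, tolerance = 1e-3)
    pw <- vapply(c(20, 60, 129, 300), powerCorrelation, numeric(1),
                 rho = 0.27)
    expect_true(all(diff(pw) > 0))
    pw2 <- vapply(c(0.1, 0.27, 0.5), powerCorrelation, numeric(1), n = 129)
    expect_true(all(diff(pw2) > 0))
})

test_that("patient-wise permutation keeps hemisphere fields together", {
    tiny <- tinyStudy()
    co <- tiny$cohort
    expect_equal(length(cohortFields(co)), 2L * nPatients(co))
    expect_equal(as.integer(table(co@fieldPatient)),
                 rep(2L, nPatients(co)))
    expect_equal(attr(tiny$peaks, "fieldIndex")[1:4], 1:4)
    stat <- function(m) max(m@stats[["bradykinesia"]]$rho, na.rm = TRUE)
    pt <- permutationTest(co, tiny$atlas, stat, nPerm = 19, seed = 3,
                          minPatients = 8L)
    pt2 <- permutationTest(co, tiny$atlas, stat, nPerm = 19, seed = 3,
                           minPatients = 8L)
    expect_identical(pt, pt2)                     # seed-stable
    expect_equal(pt$p, (1 + sum(pt$null >= pt$observed)) / 20)
    # a statistic blind to improvements has a degenerate null: p = 1
    ptc <- permutationTest(co, tiny$atlas, function(m) 1, nPerm = 9,
                           seed = 1, minPatients = 8L)
    expect_equal(ptc$p, 1)
})
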