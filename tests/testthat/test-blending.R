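test_that("fiber scores rank-correlate landscapes with field peaks", {
    tiny <- tinyStudy()
    f <- cohortFields(tiny$cohort)[[1]]
    fs <- fiberScore(f, tiny$model, "bradykinesia")
    expect_true(abs(fs$value) <= 1)
    # rank-identical peak profile gives value 1 regardless of magnitudes
    expect_equal(fibertune:::.fiberScoreValue(c(0.3, 0.1, 0.2),
                                              c(1.0, 0.2, 0.4))$value, 1)
    # a field far from every selected fiber is degenerate with value 0
    far <- EFieldGrid(array(0, c(3, 3, 3)), c(500, 500, 500), c(1, 1, 1))
    fs0 <- fiberScore(far, tiny$model, "bradykinesia")
    expect_true(fs0$degenerate)
    expect_equal(fs0$value, 0)
    # matches an independently coded rank correlation on random draws
    set.seed(21)
    for (i in 1:100) {
        rho <- rnorm(12)
        pk <- rexp(12)
        got <- fibertune:::.fiberScoreValue(rho, pk)$value
        expect_equal(got, cor(rank(rho), rank(pk)), tolerance = 1e-12)
    }
})

test_that("linear maps are ordinary least squares with degenerate guard", {
    m <- fitLinearMap(c(0, 1, 0.5), c(20, 60, 40))
    expect_equal(m$slope, 40, tolerance = 1e-9)
    expect_equal(m$intercept, 20, tolerance = 1e-9)
    m2 <- fitLinearMap(c(0, 1, 0.5), c(20, 60, 40) + 7)
    expect_equal(m2$slope, m$slope, tolerance = 1e-9)
    expect_equal(m2$intercept, m$intercept + 7, tolerance = 1e-9)
    # 5-point case against hand normal equations
    x <- c(0.1, 0.4, 0.2, 0.8, 0.5)
    y <- c(12, 35, 15, 70, 42)
    sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    m3 <- fitLinearMap(x, y)
    expect_equal(m3$slope, sl, tolerance = 1e-9)
    expect_equal(m3$intercept, mean(y) - sl * mean(x), tolerance = 1e-9)
    md <- fitLinearMap(rep(0.2, 5), y)
    expect_true(md$degenerate)
    expect_equal(md$slope, 0)
    expect_equal(md$intercept, mean(y))
    expect_error(fitLinearMap(c(0, 1), c(1, 2)), ">= 3")
})

test_that("blending weights by normalized baselines and renormalizes", {
    est <- c(tremor = 50, bradykinesia = 40, rigidity = 30, axial = 20)
    bl <- c(tremor = 4, bradykinesia = 16, rigidity = 8, axial = 12)
    expect_equal(blendEstimate(est, bl), 33)   # weights .1 .4 .2 .3
    # invariant to symptom order and uniform baseline scaling
    perm <- c(3, 1, 4, 2)
    expect_equal(blendEstimate(est[perm], bl[perm]), 33)
    expect_equal(blendEstimate(est, bl * 10), 33)
    # missing estimates are dropped with weights renormalized
    est2 <- est; est2["tremor"] <- NA
    expect_equal(blendEstimate(est2, bl),
                 sum(c(40, 30, 20) * c(16, 8, 12)) / 36)
    expect_equal(blendEstimate(c(axial = 25), c(axial = 9)), 25)
    expect_error(blendEstimate(est, bl * 0), "baseline")
})

test_that("patient prediction composes scores, maps and blending", {
    tiny <- tinyStudy()
    co <- tiny$cohort
    fields <- cohortFields(co)[1:2]
    bl <- vapply(symptomNames(co), function(s)
        patients(co)[[paste0("baseline_", s)]][1], numeric(1))
    syms <- symptomNames(co)
    pr <- predictPatient(fields, tiny$model, tiny$maps[syms], bl)
    # manual composition of fiber score -> map -> blend
    est <- vapply(syms, function(sym) {
        fs <- mean(vapply(fields, function(f)
            fiberScore(f, tiny$model, sym)$value, numeric(1)))
        min(max(tiny$maps[[sym]]$intercept + tiny$maps[[sym]]$slope * fs,
                -50), 100)
    }, numeric(1))
    expect_equal(pr$estimates, est, tolerance = 1e-12)
    expect_equal(pr$blended, blendEstimate(est, bl), tolerance = 1e-12)
    # identical fields on both sides reduce to the single-field estimate
    pr2 <- predictPatient(fields[c(1, 1)], tiny$model, tiny$maps[syms], bl)
    pr3 <- predictPatient(fields[1], tiny$model, tiny$maps[syms], bl)
    expect_equal(pr2$blended, pr3$blended, tolerance = 1e-12)
})

test_that("cross-validation estimates out-of-fold without leakage", {
    tiny <- tinyStudy()
    cv <- cvConfig(k = 4, seed = 11)
    res <- crossvalidate(tiny$cohort, tiny$atlas, cv = cv,
                         peaks = tiny$peaks, minPatients = 8L)
    expect_equal(nrow(res$estimates), nPatients(tiny$cohort))
    expect_true(all(!is.na(res$estimates$estimate)))
    res2 <- crossvalidate(tiny$cohort, tiny$atlas, cv = cv,
                          peaks = tiny$peaks, minPatients = 8L)
    expect_identical(res$estimates, res2$estimates)   # seed-stable folds
    # corrupting one patient's improvements must not change their own
    # out-of-fold estimate (their scores never enter their training folds)
    co2 <- tiny$cohort
    vic <- res$estimates$fold == res$estimates$fold[1]
    impCols <- grep("^improvement_", names(co2@patients))
    co2@patients[vic, impCols] <- co2@patients[vic, impCols] + 40
    res3 <- crossvalidate(co2, tiny$atlas, cv = cv, peaks = tiny$peaks,
                          minPatients = 8L)
    expect_identical(res$estimates$estimate[vic], res3$estimates$estimate[vic])
    # leave-one-out is the k = n special case
    resLoo <- crossvalidate(tiny$cohort, tiny$atlas,
                            cv = cvConfig(k = nPatients(tiny$cohort),
                                          seed = 2),
                            peaks = tiny$peaks, minPatients = 8L)
    expect_equal(as.integer(table(resLoo$estimates$fold)),
                 rep(1L, nPatients(tiny$cohort)))
})

test_that("shuffled improvements destroy cross-validated estimation", {
    tiny <- tinyStudy()
    co <- tiny$cohort
    impCols <- grep("^improvement_", names(co@patients))
    Rs <- vapply(1:6, function(r) {
        set.seed(100 + r)
        co@patients[impCols] <- co@patients[sample(nPatients(co)), impCols]
        crossvalidate(co, tiny$atlas, cv = cvConfig(k = 4, seed = r),
                      selection = selectionConfig(significantOnly = FALSE),
                      peaks = tiny$peaks, minPatients = 8L)$summary$R
    }, numeric(1))
    expect_lt(mean(Rs, na.rm = TRUE), 0.25)
})

test_that("field similarity is scale-invariant and needs shared support", {
    tiny <- tinyStudy()
    g <- cohortFields(tiny$cohort)[[1]]
    expect_equal(efieldSimilarity(g, g), 1, tolerance = 1e-12)
    g2 <- EFieldGrid(gridValues(g) * 2, gridOrigin(g), gridSpacing(g))
    expect_equal(efieldSimilarity(g, g2), 1, tolerance = 1e-9)
    gm <- mirror(g)
    expect_lt(abs(efieldSimilarity(g, gm)), 0.35)   # disjoint support
    far <- EFieldGrid(array(0, c(3, 3, 3)), c(500, 0, 0), c(1, 1, 1))
    expect_error(efieldSimilarity(far, far), "floor")
})

test_that("monopolar rank validation recovers setting rankings", {
    tiny <- tinyStudy()
    mr <- generateMonopolarReview(tiny$atlas, tiny$truth, tiny$sc,
                                  nElectrodes = 4, seed = 5)
    syms <- symptomNames(tiny$cohort)
    w <- setNames(rep(1, length(syms)), syms)
    elecs <- lapply(mr, function(e)
        list(fields = e$fields, empirical = rowMeans(e$empirical[, syms])))
    res <- monopolarRankValidation(elecs, tiny$model, tiny$maps, w)
    expect_length(res$R, 4L)
    # constant (e.g. fully clipped) estimates are flagged, never correlated
    expect_true(all(is.na(res$R) == res$flagged))
    # one-sample t matches its closed form on the returned R list
    Rok <- res$R[!is.na(res$R)]
    if (length(Rok) >= 2L && sd(Rok) > 0)
        expect_equal(res$t, mean(Rok) / (sd(Rok) / sqrt(length(Rok))),
                     tolerance = 1e-9)
    # estimates identical to empirical give R = 1 everywhere
    ideal <- lapply(elecs, function(e) {
        e2 <- e
        e2$empirical <- seq_along(e$fields)
        e2
    })
    resIdeal <- monopolarRankValidation(list(list(
        fields = elecs[[1]]$fields,
        empirical = res$estimates[[1]])), tiny$model, tiny$maps, w)
    expect_equal(resIdeal$R[1], 1, tolerance = 1e-9)
    expect_error(monopolarRankValidation(list(list(
        fields = elecs[[1]]$fields[1:2], empirical = 1:2)),
        tiny$model, tiny$maps, w), "fewer than 3")
})
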