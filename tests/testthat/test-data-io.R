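test_that("expression load/write round-trips and rejects malformed input", {
    x <- matrix(c(1.5, 2, 3, 4, 5, 6.25, 7, 8, 9, 10, 11, 12), 3, 4,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
    f <- tempfile(fileext = ".tsv")
    writeExpression(x, f)
    expect_message(back <- readExpression(f), "3 genes x 4 samples")
    expect_identical(back, x)

    # transposed file with the orientation flag gives the same matrix
    ft <- tempfile(fileext = ".tsv")
    writeResultTable(data.frame(sample_id = colnames(x), t(x),
                                check.names = FALSE), ft)
    expect_identical(
        suppressMessages(readExpression(ft, orientation = "samples_rows")),
        x)

    # duplicate gene id is a hard error naming the id
    fd <- tempfile(fileext = ".tsv")
    writeLines(c("gene\ts1\ts2", "gA\t1\t2", "gA\t3\t4", "gB\t5\t6"), fd)
    expect_error(readExpression(fd), "gA")

    # non-numeric cell names row and column
    fn <- tempfile(fileext = ".tsv")
    writeLines(c("gene\ts1\ts2", "gA\t1\toops", "gB\t5\t6"), fn)
    expect_error(readExpression(fn), "'gA'.*'s2'")

    # empty file
    fe <- tempfile(fileext = ".tsv")
    file.create(fe)
    expect_error(readExpression(fe), "empty")

    # missing values: reject by default, impute per-gene mean on request
    fm <- tempfile(fileext = ".tsv")
    writeLines(c("gene\ts1\ts2\ts3", "gA\t1\tNA\t3", "gB\t4\t5\t6"), fm)
    expect_error(readExpression(fm), "missing value")
    imp <- suppressMessages(readExpression(fm, impute = TRUE))
    expect_equal(imp["gA", "s2"], 2)
})

test_that("stage partition follows the three-week design", {
    part <- partitionStages(3:17)
    expect_equal(unname(part$stageOfWeek[c("3", "8", "17")]), c(1L, 2L, 5L))
    expect_equal(nrow(part$stages), 5L)
    expect_equal(part$stages$week_min, c(3, 6, 9, 12, 15))
    expect_equal(part$stages$week_max, c(5, 8, 11, 14, 17))

    # one stage per week
    p1 <- partitionStages(3:7, weeksPerStage = 1L)
    expect_equal(unname(p1$stageOfWeek), 1:5)

    # weeks below the first analyzed week are rejected
    expect_error(partitionStages(c(2, 5)), "below firstWeek")

    # partition property: stages disjoint, union covers all mapped weeks
    weeks <- sample(3:17, 40, replace = TRUE)
    p <- partitionStages(weeks)
    byStage <- split(as.integer(names(p$stageOfWeek)), p$stageOfWeek)
    expect_equal(sort(unlist(byStage, use.names = FALSE)),
                 sort(unique(weeks)))
    expect_true(all(table(unlist(byStage)) == 1))
    for (s in names(byStage))  # contiguity within a stage
        expect_true(all(diff(sort(byStage[[s]])) >= 1))
})

test_that("stage subsetting keeps aligned samples and needs both arms", {
    se <- tinyFixture()
    part <- partitionStages(SummarizedExperiment::colData(se)$week,
                            weeksPerStage = 3L, firstWeek = 3L)
    sub <- stageSubset(se, part, 1L)
    expect_equal(ncol(sub), 8L)
    expect_error(stageSubset(se, part, 9L), "not present")

    # union over stages covers every sample exactly once
    part2 <- partitionStages(SummarizedExperiment::colData(se)$week,
                             weeksPerStage = 1L, firstWeek = 3L)
    got <- unlist(lapply(part2$stages$stage, function(s)
        colnames(stageSubset(se, part2, s))))
    expect_setequal(got, colnames(se))
    expect_equal(anyDuplicated(got), 0L)

    # a stage missing one condition is an error
    seT <- se[, SummarizedExperiment::colData(se)$condition == "treatment"]
    expect_error(stageSubset(seT, part, 1L), "lacks treatment or control")
})

test_that("volcano classification is total, exclusive and matches the rule", {
    expect_equal(classifyDEG(2.0, 0.01), "sigUp")
    expect_equal(classifyDEG(-2.0, 0.01), "sigDown")
    expect_equal(classifyDEG(0.5, 0.01), "P_Only")
    expect_equal(classifyDEG(0.5, 0.5), "NoDiff")
    expect_equal(classifyDEG(1.5, 0.2), "FC_UpOnly")
    expect_equal(classifyDEG(-1.0, 0.2), "FC_DownOnly")  # >= for FC-only
    expect_error(classifyDEG(NaN, 0.5), "finite")
    expect_error(classifyDEG(1, 2), "\\[0, 1\\]")

    # total function over a grid straddling every boundary
    grid <- expand.grid(lfc = c(-3, -1.5, -1, -0.99, 0, 0.99, 1, 1.5, 3),
                        p = c(0, 0.01, 0.049, 0.05, 0.5, 1))
    cats <- classifyDEG(grid$lfc, grid$p)
    expect_true(all(cats %in% c("sigUp", "sigDown", "FC_UpOnly",
                                "FC_DownOnly", "P_Only", "NoDiff")))
    expect_equal(length(cats), nrow(grid))
})

test_that("fold changes use the pseudo-count and degTable classifies", {
    se <- tinyFixture()
    lfc <- log2FoldChange(se)
    # g1: treatment mean 9.5, control mean 2.5 -> log2(10.5/3.5)
    expect_equal(unname(lfc["g1"]), log2(10.5 / 3.5))
    expect_equal(unname(lfc["g5"]), 0)  # constant gene

    p <- setNames(c(0.01, 0.5, 0.5, 0.5, 1, 0.5), paste0("g", 1:6))
    tab <- degTable(se, p)
    expect_equal(tab$category[tab$gene_id == "g1"], "sigUp")
    expect_error(degTable(se, unname(p)[1:3]), "one value per gene")
})
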