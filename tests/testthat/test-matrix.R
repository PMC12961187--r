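mk_species_table <- function(counts, labels = NULL) {
    # counts: matrix rows = taxa, named columns = samples
    if (is.null(labels)) labels <- sprintf("Gen%s spa", letters[seq_len(nrow(counts))])
    df <- data.frame(label = labels, stringsAsFactors = FALSE)
    df$members <- lapply(labels, function(l) strsplit(l, "/", fixed = TRUE)[[1]])
    for (s in colnames(counts)) df[[s]] <- as.integer(counts[, s])
    df
}

mani4 <- sample_manifest(c("repA1", "repA2", "pos", "neg"),
                         role = c("sample", "sample", "positive_control",
                                  "negative_control"),
                         replicate_group = c("g1", "g1", NA, NA))

test_that("badges follow the P/N/S truth table exhaustively", {
    # all 16 detection patterns over {2 replicates, 1 positive, 1 negative}
    for (code in 0:15) {
        pat <- as.integer(intToBits(code))[1:4]
        counts <- matrix(pat * 5L, nrow = 1,
                         dimnames = list(NULL, mani4$sample_id))
        m <- build_matrix(mk_species_table(counts), mani4)
        b <- m$badges[[1]]
        expect_equal("P" %in% b, pat[3] > 0, info = paste("code", code))
        expect_equal("N" %in% b, pat[4] > 0, info = paste("code", code))
        expect_equal("S" %in% b, sum(pat[1:2]) == 1,
                     info = paste("code", code))
    }
})

test_that("species in all replicates and absent from controls get no badge", {
    counts <- matrix(c(7L, 9L, 0L, 0L), nrow = 1,
                     dimnames = list(NULL, mani4$sample_id))
    m <- build_matrix(mk_species_table(counts), mani4)
    expect_equal(m$badges[[1]], character(0))
})

test_that("global vs per-group single-replicate scope differ when other samples detect", {
    mani <- sample_manifest(c("r1", "r2", "other"),
                            role = rep("sample", 3),
                            replicate_group = c("g1", "g1", NA))
    counts <- matrix(c(5L, 0L, 8L), nrow = 1,
                     dimnames = list(NULL, mani$sample_id))
    mg <- build_matrix(mk_species_table(counts), mani)
    expect_false("S" %in% mg$badges[[1]])   # detected in a plain sample too
    counts2 <- matrix(c(5L, 0L, 0L), nrow = 1,
                      dimnames = list(NULL, mani$sample_id))
    m2 <- build_matrix(mk_species_table(counts2), mani)
    expect_true("S" %in% m2$badges[[1]])
    m3 <- build_matrix(mk_species_table(counts2), mani,
                       single_replicate_scope = "group")
    expect_true("S" %in% m3$badges[[1]])
})

test_that("results referencing unknown samples are rejected", {
    counts <- matrix(1L, 1, 1, dimnames = list(NULL, "ghost"))
    expect_error(build_matrix(mk_species_table(counts), mani4),
                 "absent from the manifest")
})

test_that("CSV export round-trips counts and badges, quoting awkward labels", {
    set.seed(81)
    counts <- matrix(rbinom(20 * 4, 50, 0.3), nrow = 20,
                     dimnames = list(NULL, mani4$sample_id))
    labels <- c(sprintf("Gen%02d spa", 1:18), "Gena spa/Genb spb",
                "Weird, comma sp")
    m <- build_matrix(mk_species_table(counts, labels), mani4)
    p <- tempfile(fileext = ".csv")
    export_csv(m, p)
    back <- parse_matrix_csv(p)
    expect_equal(back$labels, m$labels)
    expect_equal(unname(back$counts), unname(m$counts))
    expect_equal(back$badges, m$badges)
    # 1x1 round-trip
    m1 <- build_matrix(mk_species_table(matrix(3L, 1, 1,
        dimnames = list(NULL, "s1")), "Gena spa"),
        sample_manifest("s1"))
    export_csv(m1, p)
    expect_equal(unname(parse_matrix_csv(p)$counts[1, 1]), 3L)
})

test_that("matrix filtering is idempotent and can shrink complexes", {
    counts <- matrix(c(5L, 0L, 0L, 0L, 9L, 0L, 0L, 4L), nrow = 2,
                     dimnames = list(NULL, mani4$sample_id))
    m <- build_matrix(mk_species_table(counts,
                                       c("Gena spa/Genb spa", "Genc spa")),
                      mani4)
    drop_n <- function(row) !("N" %in% row$badges)
    f1 <- filter_matrix(m, predicate = drop_n)
    expect_equal(f1$labels, "Gena spa/Genb spa")
    f2 <- filter_matrix(f1, predicate = drop_n)
    expect_equal(f2$labels, f1$labels)
    expect_equal(f2$counts, f1$counts)
    # member-level filtering shrinks the complex and rebuilds the label
    keep_gena <- function(sp) startsWith(sp, "Gena")
    fm <- filter_matrix(m, member_filter = keep_gena)
    expect_equal(fm$labels[1], "Gena spa")
    # empty predicate is the identity
    expect_equal(filter_matrix(m)$labels, m$labels)
})

test_that("published-taxon comparison partitions into the five categories", {
    tax <- toy_taxonomy()
    tables <- list(
        species = {
            df <- data.frame(label = c("Gena spa", "Genb spa/Genc spa"),
                             stringsAsFactors = FALSE)
            df$members <- list("Gena spa", c("Genb spa", "Genc spa"))
            df$s1 <- c(10L, 5L)
            df
        },
        higher = data.frame(asv_id = c("asv_9", "asv_10"),
                            taxon = c("Fama", "Gend"),
                            rank = c("family", "genus"),
                            stringsAsFactors = FALSE))
    published <- data.frame(
        taxon = c("Gena spa",      # exact species row -> Single
                  "Genb spa",      # complex member -> Multiple
                  "Gena spb",      # its family appears as a clade row
                  "Genc spb",      # only a congener present -> Diff
                  "Gend",          # higher row, no species under it -> Clades
                  "Nofish spx"),   # nothing related -> Undetected
        level = c("species", "species", "species", "species", "clade",
                  "species"),
        stringsAsFactors = FALSE)
    got <- compare_to_published(tables, published, tax)
    expect_equal(got$category,
                 c("Single", "Multiple", "Clades", "Diff", "Clades",
                   "Undetected"))
    # partition: exactly one category per published taxon
    expect_true(all(got$category %in%
        c("Single", "Multiple", "Clades", "Diff", "Undetected")))
    expect_equal(nrow(got), nrow(published))
    # a published clade resolved to a member species counts as consistent
    pub2 <- data.frame(taxon = "Gena", level = "clade",
                       stringsAsFactors = FALSE)
    expect_equal(compare_to_published(tables, pub2, tax)$category, "Single")
})
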