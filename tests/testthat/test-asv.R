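test_that("dereplication counts exact duplicates and orders by abundance", {
    s <- "ACGTACGTAC"; t <- "TTGCAAGGCC"
    expect_equal(dereplicate(c(s, s, t)),
                 data.frame(sequence = c(s, t), abundance = c(2L, 1L)))
    expect_equal(nrow(dereplicate(character(0))), 0L)
    set.seed(61)
    tpl <- replicate(3, rand_dna(60))
    draws <- sample(tpl, 500, replace = TRUE, prob = c(5, 3, 2))
    der <- dereplicate(draws)
    expect_equal(nrow(der), 3L)
    expect_equal(sum(der$abundance), 500L)
    expect_equal(sort(der$abundance, decreasing = TRUE), der$abundance)
})

test_that("skew denoising absorbs error satellites and conserves abundance", {
    set.seed(62)
    tpl <- rand_dna(100)
    sat <- point_mutate(tpl, 37)
    un <- dereplicate(c(rep(tpl, 100), rep(sat, 3)))
    den <- denoise_simple(un)
    expect_equal(nrow(den), 1L)
    expect_equal(den$abundance, 103L)
    # two strong templates at distance 5: both kept
    tpl2 <- point_mutate(tpl, c(10, 20, 30, 40, 50))
    den2 <- denoise_simple(dereplicate(c(rep(tpl, 100), rep(tpl2, 90))))
    expect_equal(nrow(den2), 2L)
    expect_equal(sum(den2$abundance), 190L)
    # abundance conservation with min_abundance = 1, random satellites
    reads <- c(rep(tpl, 200), rep(tpl2, 120))
    for (k in 1:10) reads <- c(reads, point_mutate(tpl, sample(100, 1)))
    den3 <- denoise_simple(dereplicate(reads), min_abundance = 1)
    expect_equal(sum(den3$abundance), length(reads))
    expect_equal(attr(den3, "discarded_abundance"), 0L)
    # unabsorbable low-abundance sequences are discarded but accounted for
    lone <- rand_dna(100)
    den4 <- denoise_simple(dereplicate(c(rep(tpl, 50), lone)),
                           min_abundance = 2)
    expect_equal(nrow(den4), 1L)
    expect_equal(attr(den4, "discarded_abundance"), 1L)
})

test_that("planted error clouds collapse back to their templates", {
    set.seed(63)
    tpls <- c(rand_dna(90), rand_dna(90))
    reads <- character(0)
    for (tp in tpls) {
        reads <- c(reads, rep(tp, 150))
        n_err <- rpois(12, 0.9)
        for (k in seq_len(12))
            reads <- c(reads,
                       if (n_err[k] == 0) tp
                       else point_mutate(tp, sample(90, min(n_err[k], 1))))
    }
    den <- denoise_simple(dereplicate(reads))
    expect_setequal(den$sequence, tpls)
    expect_equal(sum(den$abundance), length(reads))
})

test_that("greedy long-read clustering keeps every read exactly once at threshold identity", {
    set.seed(64)
    tpl <- rand_dna(150)
    cl <- nanopore_cluster(setNames(rep(tpl, 20), sprintf("r%02d", 1:20)))
    expect_length(cl, 1L)
    expect_equal(cl[[1]]$size, 20L)
    expect_length(nanopore_cluster(setNames(tpl, "solo")), 1L)
    # two well-separated templates with noisy reads
    tpl2 <- point_mutate(tpl, seq(5, 145, by = 10))   # ~90% identity
    mk_noisy <- function(tp, n) vapply(seq_len(n), function(i)
        point_mutate(tp, sample(150, 2)), character(1))   # ~98.7% to template
    reads <- setNames(c(mk_noisy(tpl, 10), mk_noisy(tpl2, 10)),
                      sprintf("n%02d", 1:20))
    cl2 <- nanopore_cluster(reads, identity = 95)
    expect_length(cl2, 2L)
    expect_setequal(vapply(cl2, `[[`, 0L, "size"), c(10L, 10L))
    # partition property: every read in exactly one cluster
    all_ids <- unlist(lapply(cl2, `[[`, "member_ids"))
    expect_setequal(all_ids, names(reads))
    expect_equal(anyDuplicated(all_ids), 0L)
    # all member-to-centroid identities at or above the threshold
    for (c in cl2)
        for (m in c$members)
            expect_gte(mitobarcode:::.nanopore_align(m, c$centroid)$identity,
                       95)
})

test_that("consensus restores the template from noisy members", {
    set.seed(65)
    tpl <- rand_dna(120)
    ident <- list(centroid_id = "r1", centroid = tpl,
                  member_ids = sprintf("r%d", 1:5),
                  members = rep(tpl, 5), size = 5L)
    expect_equal(cluster_consensus(ident), tpl)
    # 9 correct reads + 1 substituted read: plurality wins
    bad <- point_mutate(tpl, 60)
    cl <- list(centroid_id = "r1", centroid = bad,
               member_ids = sprintf("r%d", 1:10),
               members = c(rep(tpl, 9), bad), size = 10L)
    expect_equal(cluster_consensus(cl), tpl)
    # singleton returns its read verbatim
    single <- list(centroid_id = "r1", centroid = bad,
                   member_ids = "r1", members = bad, size = 1L)
    expect_equal(cluster_consensus(single), bad)
})

test_that("consensus from 3%-error reads is nearly always near-perfect", {
    set.seed(66)
    tpl <- rand_dna(170)
    n_ok <- 0L
    n_trials <- 100L
    for (trial in seq_len(n_trials)) {
        reads <- vapply(1:30, function(i)
            mitobarcode:::.add_read_errors(tpl, "nanopore", 0.03),
            character(1))
        cl <- list(centroid_id = "r1", centroid = reads[1],
                   member_ids = sprintf("r%d", 1:30),
                   members = reads, size = 30L)
        cons <- cluster_consensus(cl)
        idt <- pairwise_alignment(cons, tpl, mode = "global")$identity
        if (idt >= 99.4) n_ok <- n_ok + 1L
    }
    expect_gte(n_ok, 95L)
})

test_that("MD5 digests match an independent implementation and normalize case", {
    expect_equal(md5_of_sequence("ACGT"),
                 "f1f8f4bf413b16ad135722aa4591043e")   # python hashlib
    expect_equal(md5_of_sequence("acgt"), md5_of_sequence("ACGT"))
    expect_false(md5_of_sequence("ACGTA") == md5_of_sequence("ACGTC"))
    expect_match(md5_of_sequence("TTTT"), "^[0-9a-f]{32}$")
})

test_that("multi-sample short-read ASV building distributes counts by sample", {
    set.seed(67)
    t1 <- rand_dna(80); t2 <- rand_dna(80)
    reads <- list(s1 = c(rep(t1, 30), rep(t2, 10)),
                  s2 = c(rep(t1, 5), rep(t2, 25), point_mutate(t2, 8)))
    asvs <- illumina_asvs(reads, min_abundance = 1)
    expect_equal(nrow(asvs$asvs), 2L)
    i1 <- match(t1, asvs$asvs$sequence)
    i2 <- match(t2, asvs$asvs$sequence)
    expect_equal(unname(asvs$counts[i1, ]), c(30L, 5L))
    expect_equal(unname(asvs$counts[i2, ]), c(10L, 26L))   # satellite absorbed
    expect_equal(asvs$asvs$md5, md5_of_sequence(asvs$asvs$sequence))
})

test_that("ASV FASTA round-trips with size annotations", {
    set.seed(68)
    reads <- list(a = rep(rand_dna(70), 12))
    asvs <- illumina_asvs(reads, min_abundance = 1)
    fa <- tempfile(fileext = ".fa")
    write_asvs(asvs, fasta = fa)
    back <- read_asv_fasta(fa)
    expect_equal(back$asvs$sequence, asvs$asvs$sequence)
    expect_equal(sum(back$counts), sum(asvs$counts))
})
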