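test_that("repetitive (low-complexity) strings are recognized", {
    expect_true(isRepetitive("ABABABAB"))
    expect_true(isRepetitive("AAAAAAA"))
    expect_false(isRepetitive("NFDENRGALNSH"))
    expect_equal(isRepetitive(c("AA", "ABC")), c(TRUE, FALSE))
})

test_that("terminus index holds every feasible prefix/suffix once", {
    set.seed(21)
    s <- rprot(20)
    ix <- buildTerminusIndex(setNames(s, "x"), 5:15)
    nonRep <- function(v) sum(!isRepetitive(v))
    pre <- vapply(5:15, function(n) substr(s, 1, n), "")
    suf <- vapply(5:15, function(n) substr(s, 21 - n, 20), "")
    expect_equal(length(ix$begin), nonRep(pre))
    expect_equal(length(ix$end), nonRep(suf))
    # brute-force content equality on random sequences
    items <- setNames(vapply(1:8, function(i) rprot(sample(15:40, 1)), ""),
                      paste0("s", 1:8))
    ix2 <- buildTerminusIndex(items, 5:10)
    for (id in names(items)) {
        L <- nchar(items[[id]])
        for (n in 5:min(10, L)) {
            p <- substr(items[[id]], 1, n)
            if (!isRepetitive(p)) expect_true(id %in% ix2$begin[[p]])
        }
    }
    expect_length(buildTerminusIndex(character(), 5:15)$begin, 0L)
})

# Two transcripts whose longest-ORF proteins share a unique 12-residue
# terminal anchor; same component, so they are mergeable.
anchorPairFixture <- function(anchor = "NFDENRGALNSH", comp = "C1") {
    set.seed(33)
    p1 <- paste0(rprot(60), anchor)
    p2 <- paste0(anchor, rprot(60))
    a <- paste0("TAA", backTx(p1))                    # ORF ends at 3' end
    b <- paste0(backTx(p2), "TAA")                    # ORF starts at 5' end
    TranscriptSet(setNames(c(a, b),
                           c(paste0(comp, "_G1_I3"), paste0(comp, "_G2_I1"))))
}

test_that("a shared unique terminal anchor yields one maximal candidate", {
    ts <- anchorPairFixture()
    mp <- findMergePairs(ts)
    expect_equal(nrow(mp), 1L)
    expect_equal(mp$upstream_id, "C1_G1_I3")
    expect_equal(mp$downstream_id, "C1_G2_I1")
    expect_equal(mp$anchor, "NFDENRGALNSH")
    expect_equal(mp$anchor_length, 12L)
})

test_that("cross-component pairs and ambiguous anchors are rejected", {
    # same anchor, different components: no candidate
    ts <- anchorPairFixture(comp = "C1")
    seqs <- as.character(transcriptSeqs(ts))
    names(seqs) <- c("C1_G1_I3", "C2_G1_I1")
    expect_equal(nrow(findMergePairs(TranscriptSet(seqs))), 0L)
    # one anchor matching two downstream partners: uniqueness violated
    set.seed(34)
    anchor <- "QWERTYKLMNPD"
    p1 <- paste0(rprot(60), anchor)
    p2 <- paste0(anchor, rprot(60))
    p3 <- paste0(anchor, rprot(55))
    ts3 <- TranscriptSet(setNames(
        c(paste0("TAA", backTx(p1)),
          paste0(backTx(p2), "TAA"), paste0(backTx(p3), "TAA")),
        c("C1_G1_I1", "C1_G2_I1", "C1_G3_I1")))
    expect_equal(nrow(findMergePairs(ts3)), 0L)
})

test_that("candidates are independent of transcript input order", {
    sim <- simulateTranscriptome(nGenes = 30, nMergeable = 3, nBroken = 0,
                                 nRepeat = 0, nChimera = 0, seed = 23)
    mp <- findMergePairs(sim$transcripts)
    set.seed(2)
    perm <- sim$transcripts[sample(length(sim$transcripts))]
    mp2 <- findMergePairs(perm)
    o <- function(d) d[order(d$upstream_id), , drop = FALSE]
    expect_equal(o(mp)[, 1:4], o(mp2)[, 1:4], ignore_attr = TRUE)
})

test_that("candidates satisfy all anchor constraints and reach a fixed point", {
    sim <- simulateTranscriptome(nGenes = 40, nMergeable = 4, nBroken = 0,
                                 nRepeat = 0, nChimera = 0, seed = 29)
    mp <- findMergePairs(sim$transcripts)
    expect_equal(nrow(mp), 4L)
    reps <- representativeProteins(sim$transcripts)
    for (i in seq_len(nrow(mp))) {
        up <- reps[[mp$upstream_id[i]]]; down <- reps[[mp$downstream_id[i]]]
        k <- mp$anchor_length[i]
        expect_false(isRepetitive(mp$anchor[i]))
        expect_equal(substr(up, nchar(up) - k + 1L, nchar(up)), mp$anchor[i])
        expect_equal(substr(down, 1L, k), mp$anchor[i])
        expect_equal(sub("_.*", "", mp$upstream_id[i]),
                     sub("_.*", "", mp$downstream_id[i]))
    }
    # fixed point: the post-merge set yields no candidate involving a
    # merged product and its own parents
    merged <- attr(mp, "mergedSet")
    mp2 <- findMergePairs(merged)
    expect_equal(nrow(mp2), 0L)
})

test_that("merging a split gene restores the original ORF", {
    sim <- simulateTranscriptome(nGenes = 20, nMergeable = 2, nBroken = 0,
                                 nRepeat = 0, nChimera = 0, seed = 31)
    mp <- findMergePairs(sim$transcripts)
    for (i in seq_len(nrow(mp))) {
        up <- mp$upstream_id[i]
        gene <- sim$truth$source_gene_id[sim$truth$transcript_id == up]
        prot <- sim$pool$protein[sim$pool$gene_id == gene]
        m <- applyMerge(sim$transcripts[up],
                        sim$transcripts[mp$downstream_id[i]], mp[i, ])
        expect_equal(transcriptIds(m),
                     paste0(up, "+", mp$downstream_id[i]))
        best <- orfTable(topOrfs(findOrfs(m), 1L))
        expect_equal(best$aa, prot)
        # merged length accounting: parents minus one anchor span
        lens <- nchar(as.character(transcriptSeqs(sim$transcripts[
            c(up, mp$downstream_id[i])])))
        expect_equal(nchar(as.character(transcriptSeqs(m))),
                     sum(lens) - 3L * mp$anchor_length[i],
                     ignore_attr = TRUE)
    }
    # stale candidate: anchor not present
    bad <- mp[1, ]; bad$anchor <- "WWWWWWWWWWWW"
    expect_error(applyMerge(sim$transcripts[bad$upstream_id],
                            sim$transcripts[bad$downstream_id], bad),
                 "stale")
})

test_that("nucleotide-space anchors merge transcript termini directly", {
    set.seed(44)
    anchor <- "ACGTTGCAGGTCAT"                     # 14-mer, 4 letters
    a <- paste0(rdna(80), anchor)
    b <- paste0(anchor, rdna(90))
    ts <- TranscriptSet(setNames(c(a, b), c("C7_G1_I1", "C7_G2_I1")))
    mp <- findMergePairs(ts, space = "nucleotide")
    expect_equal(nrow(mp), 1L)
    expect_equal(mp$anchor_length, 14L)
    m <- applyMerge(ts["C7_G1_I1"], ts["C7_G2_I1"], mp[1, ],
                    space = "nucleotide")
    expect_equal(as.character(transcriptSeqs(m)),
                 paste0(a, substr(b, 15L, nchar(b))),
                 ignore_attr = TRUE)
})
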