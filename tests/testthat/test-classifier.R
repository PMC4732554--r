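# Hand-built ORF tables and hit tables exercising each branch of the
# evidence partition.

orfRow <- function(tid, n, strand = "forward", len = 100L,
                   start = 1L + (n - 1L) * 1000L, aa = strrep("K", len)) {
    data.frame(orf_id = paste0(tid, "_ORF_", n), transcript_id = tid,
               strand = strand, frame = 1L, nt_start = start,
               nt_end = start + 3L * len - 1L, aa = aa,
               aa_length = len, ordinal = n, stringsAsFactors = FALSE)
}

test_that("best hit per ORF minimizes E-value with stable tie-breaks", {
    h <- rbind(hitRow("o1", "X", 1e-20), hitRow("o1", "Y", 1e-5),
               hitRow("o2", "P", 1e-9, bitscore = 90),
               hitRow("o2", "Q", 1e-9, bitscore = 100))
    b <- bestHitPerOrf(h)
    expect_equal(b$sseqid[b$qseqid == "o1"], "X")
    expect_equal(b$sseqid[b$qseqid == "o2"], "Q")
    # brute-force agreement on random tables
    set.seed(3)
    for (r in 1:20) {
        hh <- do.call(rbind, lapply(1:40, function(i)
            hitRow(sample(paste0("o", 1:6), 1L),
                   sample(paste0("s", 1:5), 1L),
                   10^-sample(5:40, 1L), sample(50:400, 1L))))
        b <- bestHitPerOrf(hh)
        for (q in unique(hh$qseqid)) {
            sub <- hh[hh$qseqid == q, ]
            sub <- sub[order(sub$evalue, -sub$bitscore, sub$sseqid), ]
            expect_equal(b$sseqid[b$qseqid == q], sub$sseqid[1L])
            expect_equal(b$evalue[b$qseqid == q], sub$evalue[1L])
        }
    }
})

test_that("identical duplicated ORFs are detected as a long repeat", {
    tb <- rbind(orfRow("t", 1, "reverse", aa = strrep("W", 143), len = 143),
                orfRow("t", 2, "reverse", aa = strrep("W", 143), len = 143),
                orfRow("t", 3, aa = rprot(50), len = 50))
    g <- detectLongRepeat(tb)
    expect_equal(sort(g$orf_ids), c("t_ORF_1", "t_ORF_2"))
    # three mutually distinct ORFs: no group
    set.seed(4)
    tb2 <- rbind(orfRow("t", 1, aa = rprot(60), len = 60),
                 orfRow("t", 2, aa = rprot(60), len = 60),
                 orfRow("t", 3, aa = rprot(60), len = 60))
    expect_null(detectLongRepeat(tb2))
})

test_that("two ORFs hitting one accession flag a broken ORF", {
    # the worked error pattern: two ORFs, one subject, E-values 6e-92/7e-45
    h <- rbind(hitRow("t_ORF_1", "CAN64666.1", 6e-92, 342,
                      sstart = 1, send = 144),
               hitRow("t_ORF_2", "CAN64666.1", 7e-45, 180,
                      sstart = 150, send = 271))
    br <- detectBrokenOrf(bestHitPerOrf(h), errorEvalue = 1e-10)
    expect_equal(br$subject_accession, "CAN64666.1")
    expect_equal(sort(br$orf_ids), c("t_ORF_1", "t_ORF_2"))
    # breakpoint hint is the subject-coordinate gap between the two hits
    expect_equal(br$breakpoint, c(144, 150))
    # different accessions: not a broken ORF
    h2 <- rbind(hitRow("t_ORF_1", "A1", 1e-30), hitRow("t_ORF_2", "B1", 1e-30))
    expect_null(detectBrokenOrf(bestHitPerOrf(h2)))
    # band is respected: evalues above errorEvalue do not fire
    h3 <- rbind(hitRow("t_ORF_1", "A1", 1e-9), hitRow("t_ORF_2", "A1", 1e-9))
    expect_null(detectBrokenOrf(bestHitPerOrf(h3), errorEvalue = 1e-10))
})

test_that("multi-gene flagging and the chimera strand rule", {
    # opposite strands (dual-ORF case): multi-gene, not a chimera
    tb <- rbind(orfRow("t", 1, "reverse", len = 331L, start = 1L),
                orfRow("t", 2, "forward", len = 390L, start = 1200L))
    h <- rbind(hitRow("t_ORF_1", "XP_006481016.1", 3e-126, 380),
               hitRow("t_ORF_2", "XP_007026739.1", 1e-180, 700))
    mg <- detectMultiGene(bestHitPerOrf(h), 1e-12, tb)
    expect_equal(nrow(mg$records), 2L)
    expect_false(mg$chimera)
    # same strand, non-overlapping: chimera candidate
    tb2 <- rbind(orfRow("t", 1, "reverse", len = 464L, start = 1L),
                 orfRow("t", 2, "reverse", len = 543L, start = 2000L))
    h2 <- rbind(hitRow("t_ORF_1", "XP_007042454.1", 7e-149, 500),
                hitRow("t_ORF_2", "XP_007030696.1", 1e-180, 900))
    mg2 <- detectMultiGene(bestHitPerOrf(h2), 1e-12, tb2)
    expect_true(mg2$chimera)
    # same strand but overlapping: not a chimera
    tb3 <- rbind(orfRow("t", 1, len = 200L, start = 1L),
                 orfRow("t", 2, len = 200L, start = 300L))
    mg3 <- detectMultiGene(bestHitPerOrf(h2), 1e-12, tb3)
    expect_false(mg3$chimera)
})

test_that("annotation selection avoids stopworded titles when it can", {
    th <- curationThresholds()
    h <- rbind(hitRow("o", "H1", 1e-40, stitle = "hypothetical protein X"),
               hitRow("o", "D1", 1e-35, stitle = "dnaJ protein homolog"))
    expect_equal(selectUniqueAnnotation(h, th$stopwords)$sseqid, "D1")
    # only a stopworded title available: kept anyway
    h2 <- hitRow("o", "V1", 6e-09,
                 stitle = "hypothetical protein VITISV_043422")
    expect_equal(selectUniqueAnnotation(h2, th$stopwords)$sseqid, "V1")
    # keyword match is case-insensitive
    h3 <- rbind(hitRow("o", "H1", 1e-40, stitle = "HYPOTHETICAL protein"),
                hitRow("o", "D1", 1e-35, stitle = "kinase"))
    expect_equal(selectUniqueAnnotation(h3, th$stopwords)$sseqid, "D1")
})

test_that("twice-the-score dominance makes an ORF unique over multi-gene", {
    ts <- TranscriptSet(setNames(rdna(30), "t"))  # sequences unused here
    tb <- rbind(orfRow("t", 1, len = 200L, start = 1L),
                orfRow("t", 2, len = 100L, start = 1000L))
    h <- rbind(hitRow("t_ORF_1", "A1", 1e-60, bitscore = 400),
               hitRow("t_ORF_2", "B1", 1e-30, bitscore = 150))
    cl <- classifyTranscripts(ts, h, orfs = new("OrfSet", table = tb))
    expect_equal(transcriptClasses(cl)$class, "UNIQUE_HIGH")
    expect_equal(annotationRecords(cl)$subject_accession, "A1")
    # without dominance (400 < 2 x 250) the same evidence is multi-gene
    h2 <- rbind(hitRow("t_ORF_1", "A1", 1e-60, bitscore = 400),
                hitRow("t_ORF_2", "B1", 1e-30, bitscore = 250))
    cl2 <- classifyTranscripts(ts, h2, orfs = new("OrfSet", table = tb))
    expect_equal(transcriptClasses(cl2)$class, "MULTI_GENE")
})

test_that("E-value bands split unique annotations into high and lower", {
    ts <- TranscriptSet(setNames(rdna(30), "t"))
    tb <- orfRow("t", 1, len = 80L)
    mk <- function(ev) classifyTranscripts(
        ts, hitRow("t_ORF_1", "S1", ev), orfs = new("OrfSet", table = tb))
    expect_equal(transcriptClasses(mk(1e-20))$class, "UNIQUE_HIGH")
    expect_equal(transcriptClasses(mk(5e-10))$class, "UNIQUE_LOW")
    expect_equal(transcriptClasses(mk(5e-8))$class, "NO_HIT")
    # no hits at all
    cl <- classifyTranscripts(ts, hitRow("x", "y", 1)[0, ],
                              orfs = new("OrfSet", table = tb))
    expect_equal(transcriptClasses(cl)$class, "NO_HIT")
})

test_that("the partition is total and invariant to hit-table row order", {
    sim <- simulateTranscriptome(nGenes = 30, nBroken = 2, nRepeat = 1,
                                 nMergeable = 2, nChimera = 2, nNoHit = 2,
                                 seed = 17)
    cl <- classifyTranscripts(sim$transcripts, sim$hits)
    cc <- classCounts(cl)
    expect_equal(sum(cc), length(sim$transcripts))
    expect_equal(nrow(transcriptClasses(cl)), length(sim$transcripts))
    set.seed(1)
    for (r in 1:3) {
        perm <- sim$hits[sample(nrow(sim$hits)), ]
        cl2 <- classifyTranscripts(sim$transcripts, perm)
        expect_identical(transcriptClasses(cl), transcriptClasses(cl2))
    }
})

test_that("raising the high band only promotes transcripts", {
    ts <- TranscriptSet(setNames(vapply(1:6, function(i) rdna(30), ""),
                                 paste0("t", 1:6)))
    tb <- do.call(rbind, c(
        lapply(1:6, function(i) orfRow(paste0("t", i), 1, len = 80L)),
        list(orfRow("t5", 2, len = 70L, start = 500L),
             orfRow("t6", 2, len = 70L, start = 500L))))
    h <- rbind(hitRow("t1_ORF_1", "S1", 1e-20), hitRow("t2_ORF_1", "S2", 5e-10),
               hitRow("t3_ORF_1", "S3", 5e-8),
               hitRow("t5_ORF_1", "S5", 1e-20),
               hitRow("t5_ORF_2", "S6", 5e-10, bitscore = 99),
               hitRow("t6_ORF_1", "S7", 1e-9, bitscore = 99),
               hitRow("t6_ORF_2", "S8", 2e-9, bitscore = 98))
    rank <- c(NO_HIT = 0, UNIQUE_LOW = 1, UNIQUE_HIGH = 2, MULTI_GENE = 2,
              BROKEN_ORF_ERROR = 3, LONG_REPEAT = 3)
    before <- transcriptClasses(classifyTranscripts(
        ts, h, orfs = new("OrfSet", table = tb)))$class
    after <- transcriptClasses(classifyTranscripts(
        ts, h, orfs = new("OrfSet", table = tb),
        thresholds = curationThresholds(highEvalue = 1e-7,
                                        lowerEvalue = 1e-7)))$class
    expect_true(all(rank[after] >= rank[before]))
})
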