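test_that("the gene pool is seeded, reproducible, and internally stop-free", {
    expect_equal(nrow(generateGenePool(0)), 0L)
    p1 <- generateGenePool(15, seed = 3)
    p2 <- generateGenePool(15, seed = 3)
    expect_identical(p1, p2)
    expect_false(identical(p1, generateGenePool(15, seed = 4)))
    # translate-and-check: every CDS translates back to its protein
    for (i in seq_len(nrow(p1)))
        expect_equal(translateCodons(p1$cds[i]), p1$protein[i])
})

test_that("error injection books exactly the requested labels", {
    pool <- generateGenePool(20, seed = 8)
    sim <- injectErrors(pool, nBroken = 5, nRepeat = 1, nMergeable = 2,
                        nChimera = 1, nNoHit = 3, seed = 8)
    tab <- table(sim$truth$label)
    expect_equal(as.integer(tab[c("broken_orf", "long_repeat",
                                  "mergeable_pair_member", "chimera",
                                  "no_hit", "clean")]),
                 c(5L, 1L, 4L, 1L, 3L, 10L))
    expect_equal(length(sim$transcripts), nrow(sim$truth))
    # lesion positions present exactly for broken-ORF records
    expect_identical(!is.na(sim$truth$lesion_position),
                     sim$truth$label == "broken_orf")
    # partner references pair up symmetrically
    mg <- sim$truth[sim$truth$label == "mergeable_pair_member", ]
    expect_identical(sort(mg$transcript_id), sort(mg$partner_id))
    # all-zero spec: everything clean
    sim0 <- injectErrors(pool, seed = 8)
    expect_true(all(sim0$truth$label == "clean"))
})

test_that("simulation is byte-identical across runs with one seed", {
    a <- simulateTranscriptome(nGenes = 15, nBroken = 1, nRepeat = 1,
                               nMergeable = 1, nChimera = 1, seed = 12)
    b <- simulateTranscriptome(nGenes = 15, nBroken = 1, nRepeat = 1,
                               nMergeable = 1, nChimera = 1, seed = 12)
    expect_identical(as.character(transcriptSeqs(a$transcripts)),
                     as.character(transcriptSeqs(b$transcripts)))
    expect_identical(a$truth, b$truth)
    expect_identical(a$hits, b$hits)
    expect_identical(a$counts, b$counts)
})

test_that("mock hits mirror the planted geometry", {
    sim <- simulateTranscriptome(nGenes = 20, nBroken = 2, nRepeat = 0,
                                 nMergeable = 0, nChimera = 0, nNoHit = 2,
                                 seed = 13)
    hits <- sim$hits
    truth <- sim$truth
    # clean transcript: exactly one strong hit, on its longest ORF
    clean <- truth$transcript_id[truth$label == "clean"][1]
    hcl <- hits[startsWith(hits$qseqid, paste0(clean, "_ORF_")), ]
    expect_equal(nrow(hcl), 1L)
    expect_lt(hcl$evalue, 1e-12)
    # broken transcript: two hits, same accession, abutting subject ranges
    for (br in truth$transcript_id[truth$label == "broken_orf"]) {
        hbr <- hits[startsWith(hits$qseqid, paste0(br, "_ORF_")), ]
        expect_equal(nrow(hbr), 2L)
        expect_equal(length(unique(hbr$sseqid)), 1L)
        hbr <- hbr[order(hbr$sstart), ]
        expect_equal(hbr$sstart[2], hbr$send[1] + 1L)
    }
    # no-hit transcripts contribute no rows
    for (nh in truth$transcript_id[truth$label == "no_hit"])
        expect_equal(sum(startsWith(hits$qseqid, paste0(nh, "_ORF_"))), 0L)
})

test_that("the mock E-value map is monotone decreasing in match length", {
    ev <- txcurate:::.mockEvalue(10:100)
    expect_true(all(diff(ev) < 0))
    expect_true(all(ev > 0))
})

test_that("simulated artifacts round trip through their file forms", {
    out <- file.path(tempdir(), "simout")
    sim <- simulateTranscriptome(nGenes = 10, nBroken = 1, nRepeat = 0,
                                 nMergeable = 1, nChimera = 0, seed = 14,
                                 outDir = out)
    ts <- readTranscripts(file.path(out, "transcripts.fasta"))
    expect_identical(as.character(transcriptSeqs(ts)),
                     as.character(transcriptSeqs(sim$transcripts)))
    h <- readHits(file.path(out, "hits.tsv"))
    expect_equal(h$qseqid, sim$hits$qseqid)
    expect_equal(h$evalue, sim$hits$evalue, tolerance = 1e-6)
    ct <- readCounts(file.path(out, "counts.tsv"))
    expect_equal(ct$raw, sim$counts$raw)
})
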