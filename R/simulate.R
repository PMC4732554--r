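## Seeded synthetic transcriptomes with ground truth.
##
## The generator plants every error class the curation workflow detects,
## at known positions, and derives a mock homology-hit table directly from
## the construction, so the whole pipeline is testable offline. Coding
## regions are flanked in-frame by stop codons, making each planted ORF
## exactly its protein; UTR context is random sequence (50-300 nt by
## default), providing realistic decoy ORFs for top-3 selection.

.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

## Synonymous codons of the standard genetic code, per amino acid.
.SYNS <- local({
    gc <- Biostrings::GENETIC_CODE
    split(names(gc), unname(gc))[.AA20]
})
.STOP <- "TAA"

.randAa <- function(n) paste(sample(.AA20, n, replace = TRUE), collapse = "")
.randNt <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                             collapse = "")
## Seeded random synonymous codon usage. A fixed codon per amino acid would
## leave the reverse strand of every CDS nearly stop-free (none of the
## chosen codons can contain a reverse-frame stop), letting long
## reverse-strand decoy ORFs displace genuine coding evidence from the
## top-3 selection; varied codons make the reverse strand behave like
## random sequence.
.backTranslate <- function(prot) {
    ch <- strsplit(prot, "", fixed = TRUE)[[1L]]
    paste(vapply(ch, function(a) {
        syn <- .SYNS[[a]]
        if (length(syn) == 1L) syn else sample(syn, 1L)
    }, "", USE.NAMES = FALSE), collapse = "")
}
.rc <- function(s) as.character(reverseComplement(DNAString(s)))

## A synonymous codon at Hamming distance 1 from `codon`, or NA.
.synNeighbour <- function(codon, aa) {
    for (alt in setdiff(.SYNS[[aa]], codon)) {
        d <- sum(strsplit(alt, "")[[1L]] != strsplit(codon, "")[[1L]])
        if (d == 1L) return(alt)
    }
    NA_character_
}

#' Generate a pool of synthetic genes
#'
#' Seeded, reproducible synthetic proteins with deterministically
#' back-translated coding sequences (stop-free internally by construction
#' of the codon table).
#'
#' @param nGenes Number of genes.
#' @param lengthRange Protein length range in residues (default 150-350,
#'   typical single-domain plant protein sizes).
#' @param seed Integer seed; the pool is byte-identical across runs with
#'   the same seed.
#' @return \code{data.frame}: \code{gene_id}, \code{accession},
#'   \code{title}, \code{protein}, \code{cds} (no stop codon included).
#' @export
generateGenePool <- function(nGenes, lengthRange = c(150L, 350L), seed = 1L) {
    set.seed(seed)
    if (nGenes == 0L)
        return(data.frame(gene_id = character(), accession = character(),
                          title = character(), protein = character(),
                          cds = character(), stringsAsFactors = FALSE))
    lens <- sample(lengthRange[1L]:lengthRange[2L], nGenes, replace = TRUE)
    prot <- vapply(lens, .randAa, "")
    data.frame(gene_id = sprintf("SYNG%04d", seq_len(nGenes)),
               accession = sprintf("SYNP%04d.1", seq_len(nGenes)),
               title = sprintf("synthetic reference protein %d [Synthetica]",
                               seq_len(nGenes)),
               protein = prot,
               cds = vapply(prot, .backTranslate, "", USE.NAMES = FALSE),
               stringsAsFactors = FALSE)
}

## Helper: one coding-segment record (forward-axis nt coords on the
## transcript; prot coords on the source protein).
.seg <- function(tid, acc, title, strand, ntStart, ntEnd, pStart, pEnd)
    data.frame(transcript_id = tid, accession = acc, title = title,
               strand = strand, nt_start = ntStart, nt_end = ntEnd,
               prot_start = pStart, prot_end = pEnd,
               stringsAsFactors = FALSE)

#' Inject labelled errors into synthetic transcripts
#'
#' Builds one transcript per clean gene and plants the error classes the
#' workflow detects: \code{broken_orf} (single-nucleotide insertion at a
#' mid-CDS codon boundary, splitting the ORF), \code{long_repeat} (exact
#' reverse-complement duplication of the CDS within one transcript),
#' \code{mergeable_pair_member} (one CDS cut into two same-component
#' transcripts sharing a unique terminal anchor, with one synonymous
#' single-nucleotide difference inside the anchor region), \code{chimera}
#' (two CDS concatenated on one strand) and \code{no_hit} (random
#' non-coding sequence). Gene consumption: broken/repeat/mergeable use one
#' gene each, chimeras two; remaining genes become clean transcripts.
#'
#' @param pool Gene pool from [generateGenePool()].
#' @param nBroken,nRepeat,nMergeable,nChimera,nNoHit Counts per label.
#' @param seed Integer seed for UTRs, lesion positions and counts.
#' @param utrRange UTR length range in nt (default 50-300).
#' @param anchorAa Anchor length (residues) planted for mergeable pairs
#'   (default 12).
#' @return List with \code{transcripts} (a [TranscriptSet-class] carrying
#'   simulated raw counts), \code{truth} (\code{data.frame}:
#'   \code{transcript_id}, \code{label}, \code{source_gene_id},
#'   \code{partner_id}, \code{lesion_position}) and \code{segments}
#'   (coding-segment map consumed by [emitMockHits()]).
#' @export
injectErrors <- function(pool, nBroken = 0L, nRepeat = 0L, nMergeable = 0L,
                         nChimera = 0L, nNoHit = 0L, seed = 1L,
                         utrRange = c(50L, 300L), anchorAa = 12L) {
    need <- nBroken + nRepeat + nMergeable + 2L * nChimera
    stopifnot(need <= nrow(pool))
    set.seed(seed + 1L)
    utr <- function() .randNt(sample(utrRange[1L]:utrRange[2L], 1L))
    gi <- 0L                      # next unconsumed pool gene
    nextGene <- function() { gi <<- gi + 1L; pool[gi, ] }
    comp <- 0L
    nextComp <- function() { comp <<- comp + 1L; sprintf("C%05d", comp) }

    seqs <- character(); truth <- list(); segs <- list()
    addT <- function(id, seq, label, gene = NA_character_,
                     partner = NA_character_, lesion = NA_integer_) {
        seqs[[id]] <<- seq
        truth[[length(truth) + 1L]] <<- data.frame(
            transcript_id = id, label = label, source_gene_id = gene,
            partner_id = partner, lesion_position = lesion,
            stringsAsFactors = FALSE)
    }
    addS <- function(s) segs[[length(segs) + 1L]] <<- s

    ## Ground-truth contract: planted evidence must be visible to the
    ## pipeline, i.e. every coding segment is fully covered, in phase, by
    ## one of the transcript's three longest ORFs. Random UTR context can
    ## by chance spawn decoy ORFs (often spanning UTR plus an off-frame
    ## read-through of the coding region) that displace planted evidence
    ## from the top three; such draws are rejected and the context
    ## resampled. All draws come from the one seeded RNG stream, so the
    ## output stays deterministic.
    segsVisible <- function(sq, sgs) {
        tb <- orfTable(topOrfs(findOrfs(sq), 3L))
        h <- .segHits(tb, sgs)
        grp <- paste(sgs$transcript_id, sgs$accession,
                     sgs$prot_start, sgs$prot_end)
        for (gkey in unique(grp)) {
            j <- which(grp == gkey)[1L]
            full <- h$sseqid == sgs$accession[j] &
                h$sstart == sgs$prot_start[j] &
                h$send == sgs$prot_end[j] &
                startsWith(h$qseqid,
                           paste0(sgs$transcript_id[j], "_ORF_"))
            if (sum(full) < sum(grp == gkey)) return(FALSE)
        }
        TRUE
    }
    attempt <- function(what, build, tries = 30L) {
        for (t in seq_len(tries)) {
            r <- build()
            if (!is.null(r)) return(r)
        }
        stop("could not realize a ", what, " transcript whose planted ",
             "evidence survives top-3 ORF selection; widen the gene ",
             "length range or shorten UTRs")
    }

    for (i in seq_len(nBroken)) {
        g <- nextGene(); id <- paste0(nextComp(), "_G1_I1")
        La <- nchar(g$protein)
        h <- La %/% 2L                      # insertion after codon h
        r <- attempt("broken-ORF", function() {
            u5 <- utr(); u3 <- utr()
            cds <- .backTranslate(g$protein)   # fresh codon realization
            cdsStart <- nchar(u5) + 4L      # after in-frame upstream stop
            body <- paste0(u5, .STOP, cds, .STOP, u3)
            p <- cdsStart + 3L * h          # inserted base position
            sq <- paste0(substr(body, 1L, p - 1L),
                         sample(c("A", "C", "G", "T"), 1L),
                         substr(body, p, nchar(body)))
            sgs <- rbind(
                .seg(id, g$accession, g$title, "forward",
                     cdsStart, cdsStart + 3L * h - 1L, 1L, h),
                .seg(id, g$accession, g$title, "forward",
                     cdsStart + 3L * h + 1L, cdsStart + 3L * La,
                     h + 1L, La))
            if (!segsVisible(setNames(sq, id), sgs)) return(NULL)
            list(sq = sq, sgs = sgs, p = p)
        })
        addT(id, r$sq, "broken_orf", g$gene_id, lesion = r$p)
        addS(r$sgs)
    }
    for (i in seq_len(nRepeat)) {
        g <- nextGene(); id <- paste0(nextComp(), "_G1_I1")
        La <- nchar(g$protein)
        r <- attempt("long-repeat", function() {
            u5 <- utr(); u3 <- utr(); spacer <- .randNt(30L)
            ## reverse-strand cassette, fresh codon realization
            block <- .rc(paste0(.STOP, .backTranslate(g$protein), .STOP))
            b1 <- nchar(u5) + 1L
            b2 <- b1 + nchar(block) + nchar(spacer)
            sq <- paste0(u5, block, spacer, block, u3)
            ## coding part of each cassette excludes the flanking stops
            sgs <- rbind(
                .seg(id, g$accession, g$title, "reverse",
                     b1 + 3L, b1 + 3L + 3L * La - 1L, 1L, La),
                .seg(id, g$accession, g$title, "reverse",
                     b2 + 3L, b2 + 3L + 3L * La - 1L, 1L, La))
            if (!segsVisible(setNames(sq, id), sgs)) return(NULL)
            list(sq = sq, sgs = sgs)
        })
        addT(id, r$sq, "long_repeat", g$gene_id)
        addS(r$sgs)
    }
    for (i in seq_len(nMergeable)) {
        g <- nextGene()
        cmp <- nextComp()
        idA <- paste0(cmp, "_G1_I1"); idB <- paste0(cmp, "_G2_I1")
        La <- nchar(g$protein)
        m <- (La %/% 2L) + anchorAa          # upstream carries prot[1..m]
        k <- anchorAa
        fragA <- substr(g$protein, 1L, m)
        fragB <- substr(g$protein, m - k + 1L, La)
        aas <- strsplit(g$protein, "", fixed = TRUE)[[1L]][(m - k + 1L):m]
        r <- attempt("mergeable-pair", function() {
            u5 <- utr(); u3 <- utr()
            cds <- .backTranslate(g$protein)   # fresh codon realization
            codons <- substring(cds, 3L * (seq_len(La) - 1L) + 1L,
                                3L * seq_len(La))
            bCodons <- codons[(m - k + 1L):La]
            ## synonymous single-nt difference in the downstream anchor copy
            for (w in seq_len(k)) {
                alt <- .synNeighbour(bCodons[w], aas[w])
                if (!is.na(alt)) { bCodons[w] <- alt; break }
            }
            aSeq <- paste0(u5, .STOP, paste(codons[1:m], collapse = ""))
            bSeq <- paste0(paste(bCodons, collapse = ""), .STOP, u3)
            ## merge representatives are the longest ORFs: require the
            ## planted fragments to be exactly those
            tbA <- orfTable(topOrfs(findOrfs(setNames(aSeq, idA)), 1L))
            if (nrow(tbA) == 0L || tbA$aa[1L] != fragA) return(NULL)
            tbB <- orfTable(topOrfs(findOrfs(setNames(bSeq, idB)), 1L))
            if (nrow(tbB) == 0L || tbB$aa[1L] != fragB) return(NULL)
            list(aSeq = aSeq, bSeq = bSeq, aCds = nchar(u5) + 4L)
        })
        addT(idA, r$aSeq, "mergeable_pair_member", g$gene_id, partner = idB)
        addT(idB, r$bSeq, "mergeable_pair_member", g$gene_id, partner = idA)
        addS(.seg(idA, g$accession, g$title, "forward",
                  r$aCds, r$aCds + 3L * m - 1L, 1L, m))
        addS(.seg(idB, g$accession, g$title, "forward",
                  1L, 3L * (La - m + k), m - k + 1L, La))
    }
    for (i in seq_len(nChimera)) {
        g1 <- nextGene()
        ## partner of comparable length, so neither fused ORF dominates the
        ## other under the twice-the-score uniqueness rule: a chimera with a
        ## dominant ORF would be uniquely annotated by design, not an error
        if (gi < nrow(pool)) {
            lens <- nchar(pool$protein)
            l1 <- nchar(g1$protein)
            cand <- seq(gi + 1L, nrow(pool))
            ratio <- pmax(lens[cand], l1) / pmin(lens[cand], l1)
            pick <- cand[order(ratio)][1L]
            if (pick != gi + 1L) {
                tmp <- pool[gi + 1L, ]
                pool[gi + 1L, ] <- pool[pick, ]
                pool[pick, ] <- tmp
            }
        }
        g2 <- nextGene()
        id <- paste0(nextComp(), "_G1_I1")
        r <- attempt("chimera", function() {
            u5 <- utr(); u3 <- utr()
            cds1 <- .backTranslate(g1$protein)
            cds2 <- .backTranslate(g2$protein)
            sq <- paste0(u5, .STOP, cds1, .STOP, .STOP, cds2, .STOP, u3)
            c1 <- nchar(u5) + 4L
            c2 <- c1 + nchar(cds1) + 6L
            sgs <- rbind(
                .seg(id, g1$accession, g1$title, "forward",
                     c1, c1 + nchar(cds1) - 1L, 1L, nchar(g1$protein)),
                .seg(id, g2$accession, g2$title, "forward",
                     c2, c2 + nchar(cds2) - 1L, 1L, nchar(g2$protein)))
            if (!segsVisible(setNames(sq, id), sgs)) return(NULL)
            list(sq = sq, sgs = sgs)
        })
        addT(id, r$sq, "chimera", g1$gene_id, partner = g2$gene_id)
        addS(r$sgs)
    }
    for (i in seq_len(nNoHit)) {
        id <- paste0(nextComp(), "_G1_I1")
        addT(id, .randNt(sample(400:900, 1L)), "no_hit")
    }
    while (gi < nrow(pool)) {
        g <- nextGene(); id <- paste0(nextComp(), "_G1_I1")
        r <- attempt("clean", function() {
            u5 <- utr(); u3 <- utr()
            cds <- .backTranslate(g$protein)   # fresh codon realization
            sq <- paste0(u5, .STOP, cds, .STOP, u3)
            cdsStart <- nchar(u5) + 4L
            sgs <- .seg(id, g$accession, g$title, "forward",
                        cdsStart, cdsStart + nchar(cds) - 1L,
                        1L, nchar(g$protein))
            if (!segsVisible(setNames(sq, id), sgs)) return(NULL)
            list(sq = sq, sgs = sgs)
        })
        addT(id, r$sq, "clean", g$gene_id)
        addS(r$sgs)
    }
    truth <- do.call(rbind, truth)
    segments <- if (length(segs)) do.call(rbind, segs) else
        .seg(character(), character(), character(), character(),
             integer(), integer(), integer(), integer())
    counts <- round(rlnorm(nrow(truth), meanlog = 4, sdlog = 1.5))
    ts <- TranscriptSet(seqs, counts = setNames(counts,
                                                truth$transcript_id))
    list(transcripts = ts, truth = truth, segments = segments)
}

## Documented monotone map: longer matches get (weakly) smaller E-values,
## floored at 1e-180 to stay inside double range. Ordinal meaning only.
.mockEvalue <- function(matchAa) pmax(10^(-1.5 * matchAa), 1e-180)

## Match ORFs against planted coding segments: same transcript, same
## strand, same reading phase, >= minOverlapAa residues covered. One hit
## row per (ORF, segment) match, subject coordinates in protein space.
.segHits <- function(tb, segs, minOverlapAa = 15L) {
    rows <- list()
    for (i in seq_len(nrow(tb))) {
        o <- tb[i, ]
        ss <- segs[segs$transcript_id == o$transcript_id &
                   segs$strand == o$strand, , drop = FALSE]
        if (nrow(ss) == 0L) next
        for (j in seq_len(nrow(ss))) {
            sg <- ss[j, ]
            ## phase compatibility on the reading strand
            if (o$strand == "forward") {
                if ((o$nt_start - sg$nt_start) %% 3L != 0L) next
            } else {
                if ((sg$nt_end - o$nt_end) %% 3L != 0L) next
            }
            ovS <- max(o$nt_start, sg$nt_start)
            ovE <- min(o$nt_end, sg$nt_end)
            if (ovE - ovS + 1L < 3L * minOverlapAa) next
            mAa <- (ovE - ovS + 1L) %/% 3L
            if (o$strand == "forward") {
                qstart <- (ovS - o$nt_start) %/% 3L + 1L
                sstart <- sg$prot_start + (ovS - sg$nt_start) %/% 3L
            } else {
                qstart <- (o$nt_end - ovE) %/% 3L + 1L
                sstart <- sg$prot_start + (sg$nt_end - ovE) %/% 3L
            }
            rows[[length(rows) + 1L]] <- data.frame(
                qseqid = o$orf_id, sseqid = sg$accession,
                pident = 100, length = mAa, mismatch = 0L, gapopen = 0L,
                qstart = qstart, qend = qstart + mAa - 1L,
                sstart = sstart, send = sstart + mAa - 1L,
                evalue = .mockEvalue(mAa), bitscore = 2 * mAa,
                stitle = sg$title, stringsAsFactors = FALSE)
        }
    }
    if (length(rows) == 0L) return(.emptyHits())
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Derive a mock homology-hit table from the simulation truth
#'
#' For each of the \code{k} longest ORFs of each transcript, emits one hit
#' per planted coding segment the ORF covers in the same strand and reading
#' phase (at least \code{minOverlapAa} residues of overlap). Subject
#' coordinates are the covered protein interval, so broken-ORF transcripts
#' yield two hits on one accession with subject ranges flanking the lesion;
#' ORFs arising from UTR or random context get no hit.
#'
#' @param sim Result of [injectErrors()].
#' @param k Top ORFs per transcript to consider (default 3).
#' @param minOverlapAa Minimum covered residues for a hit (default 15).
#' @return Hit \code{data.frame} in the standard 13-column layout.
#' @export
emitMockHits <- function(sim, k = 3L, minOverlapAa = 15L) {
    tb <- orfTable(topOrfs(findOrfs(sim$transcripts), k = k))
    .segHits(tb, sim$segments, minOverlapAa)
}

#' One-call synthetic transcriptome
#'
#' Convenience wrapper: gene pool, error injection, mock hits and counts in
#' one seeded call, optionally written to disk (\code{transcripts.fasta},
#' \code{truth.tsv}, \code{hits.tsv}, \code{counts.tsv}).
#'
#' @param nGenes Pool size (default 100).
#' @param nBroken,nRepeat,nMergeable,nChimera,nNoHit Injected counts per
#'   label (defaults 5, 2, 4, 3, 0: the package's standard study
#'   conditions for truth-recovery checks).
#' @param seed Integer seed driving every random choice.
#' @param outDir Optional output directory.
#' @param ... Passed to [injectErrors()].
#' @return List with \code{pool}, \code{transcripts}, \code{truth},
#'   \code{segments}, \code{hits}, \code{counts}.
#' @export
simulateTranscriptome <- function(nGenes = 100L, nBroken = 5L, nRepeat = 2L,
                                  nMergeable = 4L, nChimera = 3L,
                                  nNoHit = 0L, seed = 42L, outDir = NULL,
                                  ...) {
    pool <- generateGenePool(nGenes, seed = seed)
    sim <- injectErrors(pool, nBroken = nBroken, nRepeat = nRepeat,
                        nMergeable = nMergeable, nChimera = nChimera,
                        nNoHit = nNoHit, seed = seed, ...)
    hits <- emitMockHits(sim)
    counts <- data.frame(transcript_id = transcriptIds(sim$transcripts),
                         raw = unname(rawCounts(sim$transcripts)),
                         stringsAsFactors = FALSE)
    out <- c(list(pool = pool), sim, list(hits = hits, counts = counts))
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeTranscripts(sim$transcripts,
                         file.path(outDir, "transcripts.fasta"))
        write.table(sim$truth, file.path(outDir, "truth.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        writeHits(hits, file.path(outDir, "hits.tsv"))
        writeCounts(counts, file.path(outDir, "counts.tsv"))
    }
    out
}

#' Compare pipeline output against injected truth
#'
#' Maps each injected label to its expected pipeline signal (clean ->
#' UNIQUE_HIGH, broken_orf -> BROKEN_ORF_ERROR, long_repeat -> LONG_REPEAT,
#' chimera -> MULTI_GENE with the chimera flag, no_hit -> NO_HIT,
#' mergeable_pair_member -> membership in a reported merge pair) and
#' tallies recovery.
#'
#' @param truth Truth table from [injectErrors()].
#' @param classification A [ClassificationResult-class].
#' @param mergePairs Merge-candidate table from [findMergePairs()].
#' @return \code{data.frame}: \code{label}, \code{n_injected},
#'   \code{n_recovered}.
#' @export
labelRecovery <- function(truth, classification, mergePairs) {
    cl <- transcriptClasses(classification)
    got <- setNames(cl$class, cl$transcript_id)
    chim <- setNames(cl$chimera_candidate, cl$transcript_id)
    inPair <- union(mergePairs$upstream_id, mergePairs$downstream_id)
    hit <- function(id, label) switch(label,
        clean = identical(got[[id]], "UNIQUE_HIGH"),
        broken_orf = identical(got[[id]], "BROKEN_ORF_ERROR"),
        long_repeat = identical(got[[id]], "LONG_REPEAT"),
        chimera = identical(got[[id]], "MULTI_GENE") && isTRUE(chim[[id]]),
        no_hit = identical(got[[id]], "NO_HIT"),
        mergeable_pair_member = id %in% inPair,
        FALSE)
    rec <- mapply(hit, truth$transcript_id, truth$label)
    agg <- aggregate(cbind(n_injected = rep(1L, nrow(truth)),
                           n_recovered = as.integer(rec)),
                     by = list(label = truth$label), FUN = sum)
    agg[order(agg$label), ]
}

#' @importFrom stats aggregate
NULL
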