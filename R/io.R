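## Readers and writers for every on-disk artifact the workflow touches:
## transcript FASTA, two-column count tables, 12/13-column tabular homology
## hits, and the categorized CSV reports.

.HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
               "qstart", "qend", "sstart", "send", "evalue", "bitscore",
               "stitle")

.emptyHits <- function() {
    data.frame(qseqid = character(), sseqid = character(),
               pident = numeric(), length = integer(),
               mismatch = integer(), gapopen = integer(),
               qstart = integer(), qend = integer(),
               sstart = integer(), send = integer(),
               evalue = numeric(), bitscore = numeric(),
               stitle = character(), stringsAsFactors = FALSE)
}

#' Read assembled transcripts from a FASTA file
#'
#' Identifiers are taken as the first whitespace-delimited token of each
#' FASTA header; sequences are uppercased. Duplicate identifiers are
#' rejected, so the set can safely key downstream tables.
#'
#' @param path Path to a FASTA file of nucleotide transcripts.
#' @return A [TranscriptSet-class] (record order preserved).
#' @seealso [writeTranscripts()]
#' @export
readTranscripts <- function(path) {
    if (!file.exists(path)) stop("no such FASTA file: ", path)
    if (file.size(path) == 0L) return(TranscriptSet(character()))
    seqs <- tryCatch(readDNAStringSet(path, format = "fasta"),
                     error = function(e)
                         stop("malformed FASTA in ", path, ": ",
                              conditionMessage(e), call. = FALSE))
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(names(seqs)))
        stop("duplicate transcript id(s) in ", path, ": ",
             paste(unique(names(seqs)[duplicated(names(seqs))]),
                   collapse = ", "))
    TranscriptSet(setNames(as.character(seqs), names(seqs)))
}

#' Write transcripts to FASTA
#'
#' @param x A [TranscriptSet-class].
#' @param path Output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeTranscripts <- function(x, path) {
    writeXStringSet(transcriptSeqs(x), path)
    invisible(path)
}

#' Split a Trinity-style transcript identifier
#'
#' Identifiers of the form \code{<component>_<gene>_<isoform>} (e.g.
#' \code{C55368_G1_I3}) are split into their parts. Non-conforming ids are
#' not fatal: the whole id becomes the component and gene/isoform are
#' \code{NA} (a message is emitted).
#'
#' @param id Character vector of transcript ids.
#' @return \code{data.frame} with columns \code{id}, \code{component},
#'   \code{gene}, \code{isoform}.
#' @examples
#' parseTranscriptId(c("C55368_G1_I3", "scaffold12"))
#' @export
parseTranscriptId <- function(id) {
    parts <- strsplit(id, "_", fixed = TRUE)
    ok <- lengths(parts) == 3L
    if (any(!ok))
        message("non-conforming transcript id(s): ",
                paste(id[!ok], collapse = ", "))
    data.frame(id = id,
               component = ifelse(ok, vapply(parts, `[`, "", 1L), id),
               gene = ifelse(ok, vapply(parts, `[`, "", 2L), NA_character_),
               isoform = ifelse(ok, vapply(parts, `[`, "", 3L), NA_character_),
               stringsAsFactors = FALSE)
}

## Component prefix = substring before the first underscore (used by the
## merge step's same-component constraint; tolerant of merged "<a>+<b>" ids).
idComponent <- function(id) sub("_.*$", "", id)

#' Read a tabular homology-hit table
#'
#' Reads the de facto 12-column tabular search format (query id, subject id,
#' percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, E-value, bit score), with an optional 13th
#' column holding the subject title verbatim. Lines starting with \code{#}
#' are skipped.
#'
#' @param path Path to a tab-separated hit table.
#' @return \code{data.frame} with columns \code{qseqid}, \code{sseqid},
#'   \code{pident}, \code{length}, \code{mismatch}, \code{gapopen},
#'   \code{qstart}, \code{qend}, \code{sstart}, \code{send}, \code{evalue},
#'   \code{bitscore}, \code{stitle} (\code{NA} when absent).
#' @export
readHits <- function(path) {
    if (!file.exists(path)) stop("no such hit table: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L) return(.emptyHits())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 12L | nf > 13L))
        stop("hit table ", path, ": expected 12 or 13 tab-separated ",
             "columns, got ", nf[which(nf < 12L | nf > 13L)[1L]],
             " at data row ", which(nf < 12L | nf > 13L)[1L])
    get <- function(i) vapply(fields, `[`, "", i)
    num <- function(i, what) {
        v <- suppressWarnings(as.numeric(get(i)))
        if (anyNA(v))
            stop("hit table ", path, ": unparseable ", what,
                 " at data row ", which(is.na(v))[1L])
        v
    }
    out <- data.frame(qseqid = get(1L), sseqid = get(2L),
                      pident = num(3L, "percent identity"),
                      length = as.integer(num(4L, "alignment length")),
                      mismatch = as.integer(num(5L, "mismatch count")),
                      gapopen = as.integer(num(6L, "gap-open count")),
                      qstart = as.integer(num(7L, "query start")),
                      qend = as.integer(num(8L, "query end")),
                      sstart = as.integer(num(9L, "subject start")),
                      send = as.integer(num(10L, "subject end")),
                      evalue = num(11L, "E-value"),
                      bitscore = num(12L, "bit score"),
                      stitle = ifelse(nf == 13L, vapply(fields, function(f)
                          if (length(f) >= 13L) f[13L] else NA_character_, ""),
                          NA_character_),
                      stringsAsFactors = FALSE)
    if (any(out$evalue < 0))
        stop("hit table ", path, ": negative E-value at data row ",
             which(out$evalue < 0)[1L])
    if (any(out$pident < 0 | out$pident > 100))
        stop("hit table ", path, ": percent identity outside [0,100] ",
             "at data row ", which(out$pident < 0 | out$pident > 100)[1L])
    out
}

#' Write a homology-hit table
#' @param hits Hit \code{data.frame} as returned by [readHits()].
#' @param path Output path (tab-separated, 13 columns when any title set).
#' @return \code{path}, invisibly.
#' @export
writeHits <- function(hits, path) {
    ## rows without a title are written with 12 columns, titled rows with 13
    core <- hits[, setdiff(.HIT_COLS, "stitle"), drop = FALSE]
    core$evalue <- format(core$evalue, scientific = TRUE, trim = TRUE,
                          digits = 7)
    lines <- do.call(paste, c(core, sep = "\t"))
    titled <- !is.na(hits$stitle)
    lines[titled] <- paste(lines[titled], hits$stitle[titled], sep = "\t")
    writeLines(lines, path)
    invisible(path)
}

#' Read a raw-count table
#'
#' @param path Two whitespace/tab-separated columns: transcript id, count.
#' @return \code{data.frame} with columns \code{transcript_id}, \code{raw}.
#' @export
readCounts <- function(path) {
    if (!file.exists(path)) stop("no such count table: ", path)
    if (file.size(path) == 0L)
        return(data.frame(transcript_id = character(), raw = numeric(),
                          stringsAsFactors = FALSE))
    df <- read.table(path, header = FALSE, colClasses = c("character", "numeric"),
                     col.names = c("transcript_id", "raw"),
                     stringsAsFactors = FALSE)
    if (any(df$raw < 0))
        stop("negative raw count for ",
             paste(df$transcript_id[df$raw < 0], collapse = ", "))
    df
}

#' Write a raw-count table
#' @param counts \code{data.frame} with \code{transcript_id} and \code{raw}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeCounts <- function(counts, path) {
    write.table(counts[, c("transcript_id", "raw")], path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write the categorized curation reports
#'
#' Emits the report bundle of a curation run. Every transcript appears in
#' exactly one of the four partition files: \code{high_annotated.csv}
#' (UNIQUE_HIGH and MULTI_GENE, which carry high-significance annotations),
#' \code{lower_annotated.csv} (UNIQUE_LOW), \code{annotated_none.csv}
#' (NO_HIT) and \code{errors.csv} (BROKEN_ORF_ERROR and LONG_REPEAT).
#' MULTI_GENE transcripts additionally get one row per annotation in
#' \code{morethanone.csv}. Merge pairs and normalized counts are written
#' when supplied.
#'
#' @param classified A [ClassificationResult-class].
#' @param outdir Output directory (created if needed).
#' @param mergePairs Optional merge-candidate \code{data.frame} from
#'   [findMergePairs()].
#' @param normCounts Optional normalized-count \code{data.frame} from
#'   [normalizeCounts()].
#' @return Named character vector of the files written, invisibly.
#' @export
writeReports <- function(classified, outdir, mergePairs = NULL,
                         normCounts = NULL) {
    ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
    if (!ok || file.access(outdir, 2L) != 0L)
        stop("cannot write to output directory: ", outdir)
    cl <- transcriptClasses(classified)
    ann <- annotationRecords(classified)
    annFor <- function(ids) {
        a <- ann[ann$transcript_id %in% ids, , drop = FALSE]
        if (nrow(a) == 0L)
            a <- data.frame(transcript_id = character(),
                            orf_id = character(), subject_accession = character(),
                            subject_title = character(), evalue = numeric(),
                            bitscore = numeric(), strand = character(),
                            stringsAsFactors = FALSE)
        ## keep transcripts that have a class but no annotation rows
        miss <- setdiff(ids, a$transcript_id)
        if (length(miss))
            a <- rbind(a, data.frame(transcript_id = miss, orf_id = NA,
                                     subject_accession = NA, subject_title = NA,
                                     evalue = NA, bitscore = NA, strand = NA,
                                     stringsAsFactors = FALSE))
        a[order(match(a$transcript_id, ids)), , drop = FALSE]
    }
    files <- c(high = "high_annotated.csv", lower = "lower_annotated.csv",
               none = "annotated_none.csv", errors = "errors.csv",
               multi = "morethanone.csv", merged = "merged_pairs.txt",
               norm = "counts_normalized.tsv")
    paths <- setNames(file.path(outdir, files), names(files))

    wcsv <- function(df, p) write.csv(df, p, row.names = FALSE, quote = TRUE)
    highIds <- cl$transcript_id[cl$class %in% c("UNIQUE_HIGH", "MULTI_GENE")]
    wcsv(annFor(highIds), paths["high"])
    wcsv(annFor(cl$transcript_id[cl$class == "UNIQUE_LOW"]), paths["lower"])
    wcsv(data.frame(transcript_id = cl$transcript_id[cl$class == "NO_HIT"]),
         paths["none"])
    errIds <- cl$transcript_id[cl$class %in% c("BROKEN_ORF_ERROR",
                                               "LONG_REPEAT")]
    err <- merge(cl[cl$transcript_id %in% errIds,
                    c("transcript_id", "class", "breakpoint_subject",
                      "breakpoint_start", "breakpoint_end")],
                 annFor(errIds), by = "transcript_id", all.x = TRUE)
    wcsv(err, paths["errors"])
    multiIds <- cl$transcript_id[cl$class == "MULTI_GENE"]
    wcsv(annFor(multiIds), paths["multi"])
    if (is.null(mergePairs))
        mergePairs <- data.frame(upstream_id = character(),
                                 downstream_id = character(),
                                 anchor = character())
    writeLines(paste(mergePairs$upstream_id, mergePairs$downstream_id,
                     mergePairs$anchor, sep = "\t"), paths["merged"])
    if (!is.null(normCounts))
        write.table(normCounts[, c("transcript_id", "raw", "length_nt",
                                   "normalized")],
                    paths["norm"], sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = TRUE)
    invisible(paths)
}

#' @importFrom utils write.csv read.table
NULL
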