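#' Read a FASTA (or FASTQ) file into an XStringSet
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] /
#' [Biostrings::readAAStringSet()] adding the package's input contract:
#' record ids are the first whitespace-delimited token of the header, must
#' be unique and non-empty, sequences are uppercased (Biostrings drops
#' case on read) and validated against the declared alphabet (DNA: ACGTN;
#' protein: the 20 amino acids plus X). FASTQ is accepted for reads;
#' qualities are ignored.
#'
#' @param path Path to a FASTA/FASTQ file.
#' @param type `"DNA"` or `"AA"`.
#' @param format `"fasta"` (default) or `"fastq"`.
#' @return A [Biostrings::DNAStringSet] or [Biostrings::AAStringSet];
#'   empty input yields an empty set.
#' @export
readFasta <- function(path, type = c("DNA", "AA"),
                      format = c("fasta", "fastq")) {
    type <- match.arg(type)
    format <- match.arg(format)
    stopifnot(file.exists(path))
    x <- if (type == "DNA")
        Biostrings::readDNAStringSet(path, format = format)
    else
        Biostrings::readAAStringSet(path, format = format)
    nm <- sub("\\s.*$", "", names(x))
    if (length(x)) {
        if (any(!nzchar(nm)))
            stop("FASTA record with empty id in ", path)
        if (anyDuplicated(nm))
            stop("duplicate FASTA id(s): ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", "))
        if (any(Biostrings::width(x) == 0L))
            stop("empty sequence under header(s): ",
                 paste(nm[Biostrings::width(x) == 0L], collapse = ", "))
        .checkAlphabet(x, type)
    }
    names(x) <- nm
    x
}

.checkAlphabet <- function(x, type) {
    ok <- if (type == "DNA") c("A", "C", "G", "T", "N")
          else c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
    af <- Biostrings::alphabetFrequency(x, collapse = TRUE)
    bad <- af[!(names(af) %in% ok) & af > 0]
    if (length(bad))
        stop("disallowed ", if (type == "DNA") "DNA" else "protein",
             " letter(s): ", paste(names(bad), collapse = ", "))
    invisible(TRUE)
}

#' Write sequences as wrapped FASTA
#'
#' @param x An XStringSet (or named character vector).
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @export
writeFasta <- function(x, path, width = 60L) {
    if (is.character(x))
        x <- Biostrings::DNAStringSet(x)
    Biostrings::writeXStringSet(x, path, width = width)
    invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Imports `gene` features via [rtracklayer::import()], orders them by
#' (chromosome, start) and assigns `rank`, the 1-based position of each
#' gene in its chromosome's gene order — the coordinate the tandem
#' gene-cluster rule operates on. Input coordinates are GFF3 1-based
#' inclusive and are kept in that convention (GRanges).
#'
#' @param path Path to a GFF3 file.
#' @return A [GenomicRanges::GRanges] sorted by (chrom, start) with
#'   metadata columns `gene_id` and `rank`. Empty/headers-only input
#'   yields an empty GRanges.
#' @export
readGffGenes <- function(path) {
    stopifnot(file.exists(path))
    .validateGffGenes(path)
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    if (!length(gr)) {
        out <- GenomicRanges::GRanges()
        mcols(out)$gene_id <- character(0)
        mcols(out)$rank <- integer(0)
        return(out)
    }
    gene_id <- as.character(gr$ID)
    out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                  IRanges::ranges(gr),
                                  strand = GenomicRanges::strand(gr))
    mcols(out)$gene_id <- gene_id
    out <- .rankGenes(out)
    out
}

## cheap pre-scan so contract errors carry a line number
.validateGffGenes <- function(path) {
    ln <- readLines(path, warn = FALSE)
    for (i in seq_along(ln)) {
        l <- ln[[i]]
        if (!nzchar(l) || startsWith(l, "#")) next
        f <- strsplit(l, "\t", fixed = TRUE)[[1]]
        if (length(f) < 9L) next
        if (f[3] != "gene") next
        s <- suppressWarnings(as.numeric(f[4]))
        e <- suppressWarnings(as.numeric(f[5]))
        if (is.finite(s) && is.finite(e) && s > e)
            stop("GFF line ", i, ": start > end")
        if (!grepl("(^|;)ID=", f[9]))
            stop("GFF line ", i, ": gene feature without ID attribute")
    }
    invisible(TRUE)
}

.rankGenes <- function(gr) {
    o <- order(as.character(GenomeInfoDb::seqnames(gr)),
               GenomicRanges::start(gr))
    gr <- gr[o]
    chrom <- as.character(GenomeInfoDb::seqnames(gr))
    mcols(gr)$rank <- stats::ave(seq_along(gr), chrom,
                                 FUN = seq_along)
    gr
}

#' Write gene models as GFF3
#'
#' @param genes GRanges with a `gene_id` metadata column.
#' @param path Output path.
#' @export
writeGffGenes <- function(genes, path) {
    g <- genes
    mcols(g) <- S4Vectors::DataFrame(
        source = "T2Tqc", type = "gene", ID = genes$gene_id,
        Name = genes$gene_id)
    rtracklayer::export(g, path, format = "gff3")
    invisible(path)
}

#' Read terminal-read alignments from a PAF file
#'
#' Parses the 12 mandatory PAF columns. PAF target coordinates are
#' 0-based half-open; they are converted once here to the package's
#' GRanges convention (1-based closed): `start = tstart + 1`,
#' `end = tend`. No R PAF reader ships with the supported stack, so the
#' (trivial, tab-delimited) format is parsed directly.
#'
#' @param path Path to a PAF file.
#' @return GRanges on the target with metadata columns `read_id`,
#'   `read_len`, `read_start`, `read_end` (read coords, 0-based half-open
#'   as in PAF), `nmatch`, `alen`, `mapq`; strand from column 5.
#' @export
readPaf <- function(path) {
    stopifnot(file.exists(path))
    ln <- readLines(path, warn = FALSE)
    ln <- ln[nzchar(ln)]
    if (!length(ln)) {
        out <- GenomicRanges::GRanges()
        mcols(out) <- S4Vectors::DataFrame(
            read_id = character(0), read_len = integer(0),
            read_start = integer(0), read_end = integer(0),
            nmatch = integer(0), alen = integer(0), mapq = integer(0))
        return(out)
    }
    f <- strsplit(ln, "\t", fixed = TRUE)
    nc <- lengths(f)
    if (any(nc < 12L))
        stop("PAF line ", which(nc < 12L)[1], ": fewer than 12 columns")
    col <- function(i) vapply(f, `[[`, character(1), i)
    num <- function(i) as.numeric(col(i))
    tstart <- num(8); tend <- num(9)
    gr <- GenomicRanges::GRanges(col(6),
        IRanges::IRanges(start = tstart + 1, end = tend),
        strand = col(5))
    mcols(gr) <- S4Vectors::DataFrame(
        read_id = col(1), read_len = as.integer(num(2)),
        read_start = as.integer(num(3)), read_end = as.integer(num(4)),
        nmatch = as.integer(num(10)), alen = as.integer(num(11)),
        mapq = as.integer(num(12)))
    mcols(gr)$tlen <- as.integer(num(7))
    gr
}

#' Write alignments as PAF
#'
#' Inverse of [readPaf()]: GRanges coordinates are converted back to
#' PAF's 0-based half-open target coordinates.
#'
#' @param aln GRanges as returned by [readPaf()].
#' @param path Output path.
#' @export
writePaf <- function(aln, path) {
    m <- mcols(aln)
    lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
        m$read_id, m$read_len, m$read_start, m$read_end,
        as.character(GenomicRanges::strand(aln)),
        as.character(GenomeInfoDb::seqnames(aln)), m$tlen,
        GenomicRanges::start(aln) - 1L, GenomicRanges::end(aln),
        m$nmatch, m$alen, m$mapq)
    writeLines(lines, path)
    invisible(path)
}

#' Read a BED3+label file of intervals
#'
#' BED is 0-based half-open; converted to GRanges (1-based closed).
#'
#' @param path Path to a BED file.
#' @return GRanges with a `label` metadata column.
#' @export
readBed <- function(path) {
    stopifnot(file.exists(path))
    ln <- readLines(path, warn = FALSE)
    ln <- ln[nzchar(ln) & !startsWith(ln, "track") & !startsWith(ln, "#")]
    if (!length(ln)) {
        out <- GenomicRanges::GRanges()
        mcols(out)$label <- character(0)
        return(out)
    }
    f <- strsplit(ln, "\t", fixed = TRUE)
    chrom <- vapply(f, `[[`, character(1), 1)
    s <- as.numeric(vapply(f, `[[`, character(1), 2))
    e <- as.numeric(vapply(f, `[[`, character(1), 3))
    lab <- vapply(f, function(x) if (length(x) >= 4) x[[4]] else ".",
                  character(1))
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s + 1, e))
    mcols(gr)$label <- lab
    gr
}

#' Write intervals as BED3+label
#'
#' @param gr GRanges; a `label` metadata column is used as column 4 when
#'   present.
#' @param path Output path.
#' @export
writeBed <- function(gr, path) {
    lab <- if (!is.null(gr$label)) gr$label else rep(".", length(gr))
    lines <- sprintf("%s\t%d\t%d\t%s",
        as.character(GenomeInfoDb::seqnames(gr)),
        GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr), lab)
    writeLines(lines, path)
    invisible(path)
}

#' Read an FPKM matrix from TSV
#'
#' First column gene ids, remaining columns samples.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with gene rownames.
#' @export
readFpkm <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    m
}
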