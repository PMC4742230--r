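#' Load single-nucleotide variants from VCF or pgSnp
#'
#' VCF (v4.x) records are parsed with \pkg{vcfR}; only single-nucleotide
#' ref/alt pairs are kept, multi-allelic records are split into one
#' variant per alternate allele, and VCF's 1-based positions become
#' 0-based. When the file carries genotypes, only alleles the first
#' sample actually carries are returned and zygosity is read from its GT;
#' without genotypes every record is kept with zygosity `"het"`. UCSC
#' pgSnp rows (0-based, observed alleles like `"A/G"`) need the reference
#' genome to polarise ref vs alt. Malformed or non-SNV records are
#' skipped and counted in the `n_skipped` attribute.
#'
#' @param path variant file.
#' @param format `"auto"` (by extension / content), `"vcf"` or `"pgsnp"`.
#' @param genome named character vector of reference sequences; required
#'   for pgSnp.
#' @return data.frame with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`, `zygosity` (`"het"`/`"hom"`), `id`; attribute `n_skipped`.
#' @export
load_variants <- function(path, format = c("auto", "vcf", "pgsnp"),
                          genome = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
    else if (any(grepl("^##fileformat=VCF", readLines(path, n = 5L)))) "vcf"
    else "pgsnp"
  }
  if (format == "vcf") load_variants_vcf(path) else load_variants_pgsnp(path, genome)
}

empty_variants <- function(n_skipped = 0L) {
  structure(data.frame(chrom = character(), pos = integer(),
                       ref = character(), alt = character(),
                       zygosity = character(), id = character(),
                       stringsAsFactors = FALSE),
            n_skipped = n_skipped)
}

load_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0) return(empty_variants())
  gt <- NULL
  if (ncol(v@gt) >= 2) {
    gt <- vcfR::extract.gt(v, element = "GT")[, 1]
  }
  rows <- list()
  n_skipped <- 0L
  for (r in seq_len(n_rec)) {
    ref <- toupper(fix[r, "REF"])
    alts <- strsplit(toupper(fix[r, "ALT"] %||% ""), ",", fixed = TRUE)[[1]]
    pos1 <- suppressWarnings(as.integer(fix[r, "POS"]))
    if (is.na(pos1) || is.na(ref) || !length(alts)) {
      n_skipped <- n_skipped + 1L
      next
    }
    g <- if (!is.null(gt)) gt[r] else NA_character_
    g_alleles <- if (!is.na(g)) strsplit(g, "[/|]")[[1]] else NULL
    any_kept <- FALSE
    for (j in seq_along(alts)) {
      alt <- alts[j]
      if (nchar(ref) != 1 || nchar(alt) != 1 ||
          !(ref %in% DNA_BASES) || !(alt %in% DNA_BASES) || ref == alt) next
      if (!is.null(g_alleles)) {
        n_copies <- sum(g_alleles == as.character(j))
        if (n_copies == 0) next
        zyg <- if (n_copies >= 2) "hom" else "het"
      } else {
        zyg <- "het"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix[r, "CHROM"], pos = pos1 - 1L, ref = ref, alt = alt,
        zygosity = zyg,
        id = if (is.na(fix[r, "ID"]) || fix[r, "ID"] == ".")
          sprintf("%s:%d:%s>%s", fix[r, "CHROM"], pos1 - 1L, ref, alt)
        else fix[r, "ID"],
        stringsAsFactors = FALSE)
      any_kept <- TRUE
    }
    if (!any_kept) n_skipped <- n_skipped + 1L
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_variants()
  if (n_skipped > 0) {
    cobel_log(sprintf("load_variants: skipped %d non-SNV/malformed record(s) in %s",
                      n_skipped, basename(path)))
  }
  attr(out, "n_skipped") <- n_skipped
  rownames(out) <- NULL
  out
}

load_variants_pgsnp <- function(path, genome) {
  if (is.null(genome)) stop("pgSnp input needs the reference 'genome'")
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "alleles")
  rows <- list()
  n_skipped <- 0L
  for (r in seq_len(nrow(df))) {
    if (df$end[r] - df$start[r] != 1) {
      n_skipped <- n_skipped + 1L
      next
    }
    alleles <- toupper(strsplit(df$alleles[r], "/", fixed = TRUE)[[1]])
    ref_base <- toupper(substr(genome[[df$chrom[r]]], df$start[r] + 1L,
                               df$start[r] + 1L))
    alts <- setdiff(alleles, ref_base)
    alts <- alts[alts %in% DNA_BASES]
    if (!length(alts) || !(ref_base %in% DNA_BASES)) {
      n_skipped <- n_skipped + 1L
      next
    }
    zyg <- if (length(alleles) == 1) "hom" else "het"
    for (alt in alts) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = df$chrom[r], pos = df$start[r], ref = ref_base, alt = alt,
        zygosity = zyg,
        id = sprintf("%s:%d:%s>%s", df$chrom[r], df$start[r], ref_base, alt),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_variants()
  attr(out, "n_skipped") <- n_skipped
  rownames(out) <- NULL
  out
}

#' Read an outgroup (ancestral proxy) base track
#'
#' Accepts a 2-column TSV (`pos`, `base`; single-chromosome shorthand),
#' a 3-column TSV (`chrom`, `pos`, `base`), or a FASTA aligned to
#' reference coordinates.
#'
#' @param path track file.
#' @param chrom chromosome name assumed for the 2-column form.
#' @return a lookup data.frame with columns `chrom`, `pos`, `base`.
#' @export
read_outgroup <- function(path, chrom = NULL) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    genome <- read_genome_fasta(path)
    out <- do.call(rbind, lapply(names(genome), function(ch) {
      data.frame(chrom = ch, pos = seq_len(nchar(genome[[ch]])) - 1L,
                 base = strsplit(genome[[ch]], "", fixed = TRUE)[[1]],
                 stringsAsFactors = FALSE)
    }))
    return(out)
  }
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) == 2) {
    if (is.null(chrom)) stop("2-column outgroup TSV needs 'chrom'")
    df <- data.frame(chrom = chrom, pos = df[[1]], base = toupper(df[[2]]),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(chrom = df[[1]], pos = df[[2]], base = toupper(df[[3]]),
                     stringsAsFactors = FALSE)
  }
  df
}

#' Keep variants whose reference allele is ancestral
#'
#' A variant passes when the outgroup has an orthologous base at its
#' position, that base equals the reference allele (so the reference is
#' most likely ancestral), and the individual's alternate allele differs
#' from it (the derived state). Variants at positions absent from the
#' outgroup track cannot be polarised and are removed.
#'
#' @param variants data.frame from [load_variants()].
#' @param outgroup lookup data.frame from [read_outgroup()].
#' @return the filtered variant data.frame.
#' @export
ancestral_filter <- function(variants, outgroup) {
  if (nrow(variants) == 0) return(variants)
  key <- paste(variants$chrom, variants$pos)
  og <- setNames(toupper(outgroup$base), paste(outgroup$chrom, outgroup$pos))
  base <- og[key]
  keep <- !is.na(base) & base %in% DNA_BASES &
    base == variants$ref & variants$alt != base
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- attr(variants, "n_skipped")
  out
}
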