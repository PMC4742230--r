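#' Read a reference-anchored MAF multiple alignment
#'
#' Parses the subset of MAF needed for conservation scanning: `a` block
#' lines followed by `s` sequence lines. Row source names are
#' `species.chrom`; the first row of every block must belong to
#' `ref_species` and be on the `+` strand (reference-anchored alignment).
#' Coordinates are 0-based half-open on the reference.
#'
#' @param path MAF file.
#' @param ref_species reference species label.
#' @return an object of class `maf_alignment`: a list of blocks, each a
#'   list with `chrom`, `start`, `end` (reference interval), `species`
#'   (character, reference first) and `seqs` (aligned rows, same order,
#'   equal length, `-` for gaps).
#' @export
read_maf <- function(path, ref_species) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function(cur, blocks) {
    if (is.null(cur) || length(cur$species) == 0) return(blocks)
    if (length(unique(nchar(cur$seqs))) != 1) {
      stop("MAF block rows have unequal aligned lengths")
    }
    if (cur$species[1] != ref_species) {
      stop("first row of each MAF block must be the reference species")
    }
    blocks[[length(blocks) + 1L]] <- cur
    blocks
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      blocks <- flush(cur, blocks)
      cur <- list(chrom = NA_character_, start = NA_integer_,
                  end = NA_integer_, species = character(), seqs = character())
    } else if (startsWith(ln, "s")) {
      if (is.null(cur)) stop("MAF 's' line before any 'a' line")
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      src <- strsplit(f[2], ".", fixed = TRUE)[[1]]
      sp <- src[1]
      chrom <- if (length(src) > 1) paste(src[-1], collapse = ".") else NA_character_
      start <- as.integer(f[3]); size <- as.integer(f[4]); strand <- f[5]
      seq <- toupper(f[7])
      if (length(cur$species) == 0) {
        if (strand != "+") stop("reference MAF row must be on the + strand")
        cur$chrom <- chrom
        cur$start <- start
        cur$end <- start + size
      }
      cur$species <- c(cur$species, sp)
      cur$seqs <- c(cur$seqs, seq)
    }
  }
  blocks <- flush(cur, blocks)
  structure(blocks, class = "maf_alignment", ref_species = ref_species)
}

#' Write a reference-anchored MAF file
#'
#' @param blocks a `maf_alignment` (or bare list of blocks as produced by
#'   [read_maf()]).
#' @param path output path.
#' @param chrom_sizes named integer vector used for the `srcSize` field;
#'   aligned rows are written with their reference chromosome source size
#'   (toy alignments reuse reference coordinates for every species).
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path, chrom_sizes) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines("a score=0.000000", con)
    src_size <- unname(chrom_sizes[b$chrom])
    for (i in seq_along(b$species)) {
      ungapped <- nchar(gsub("-", "", b$seqs[i], fixed = TRUE))
      writeLines(sprintf("s %s.%s %d %d + %d %s",
                         b$species[i], b$chrom, b$start, ungapped,
                         src_size, b$seqs[i]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' @export
print.maf_alignment <- function(x, ...) {
  cat(sprintf("MAF alignment: %d blocks, reference '%s'\n",
              length(x), attr(x, "ref_species")))
  invisible(x)
}

# Index of the block fully containing [start, end) on chrom, or NA.
find_block <- function(blocks, chrom, start, end) {
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (identical(b$chrom, chrom) && b$start <= start && b$end >= end) return(i)
  }
  NA_integer_
}

# Alignment columns of one reference position range within a block.
# Returns integer column indices (length end - start), following the
# reference row's non-gap positions.
ref_columns <- function(block, start, end) {
  ref_chars <- strsplit(block$seqs[1], "", fixed = TRUE)[[1]]
  non_gap <- which(ref_chars != "-")
  non_gap[(start - block$start + 1L):(end - block$start)]
}
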