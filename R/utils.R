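# Shared coordinate and allele-key helpers.

#' Normalize a chromosome name
#'
#' Strips a leading `"chr"` prefix and maps `"M"`/`"chrM"`/`"chrMT"` to
#' `"MT"`, so mitochondrial and prefixed contig names compare equal across
#' VCF, BED and lookup tables.
#'
#' @param chrom Character vector of contig names.
#' @return Character vector of normalized names.
#' @export
normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  x[x %in% c("M", "m", "mt")] <- "MT"
  x
}

#' Reduce a variant to its minimal representation
#'
#' Trims bases shared between REF and ALT (suffix first, then prefix,
#' keeping at least one base on each side) and adjusts the position, so that
#' the same allele written differently -- e.g. `100 CA>CT` vs `101 A>T` --
#' yields one key. Alleles are upper-cased.
#'
#' @param pos 1-based position(s).
#' @param ref,alt Allele strings (vectorized).
#' @return A data.frame with columns `pos`, `ref`, `alt`.
#' @export
normalize_allele <- function(pos, ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  pos <- as.integer(pos)
  for (i in seq_along(pos)) {
    r <- strsplit(ref[i], "", fixed = TRUE)[[1L]]
    a <- strsplit(alt[i], "", fixed = TRUE)[[1L]]
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  data.frame(pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
}

# Canonical "chrom:pos:ref:alt" key used for all membership tests.
variant_key <- function(chrom, pos, ref, alt) {
  n <- normalize_allele(pos, ref, alt)
  paste(normalize_chrom(chrom), n$pos, n$ref, n$alt, sep = ":")
}

# sample() treats a length-1 numeric as 1:x; this never does.
sample_one <- function(x) x[sample.int(length(x), 1L)]

# set.seed wrapper that restores the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
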