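#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"

# DNA alphabet and pyrimidine-collapsed substitution classes.
.bases <- c("A", "C", "G", "T")
.comp <- c(A = "T", C = "G", G = "C", T = "A")

#' Canonical substitution and context feature names
#'
#' Every single-base substitution is reported on the strand whose reference
#' base is a pyrimidine (C or T), giving 6 substitution classes. Adding the
#' genomic flanks yields 96 trinucleotide classes (`"A[C>T]G"`), 48 one-sided
#' dinucleotide classes (24 with the 5' flank, `"A[C>T]"`, and 24 with the 3'
#' flank, `"[C>T]G"`) and the 6 bare classes. The canonical column order of
#' every feature matrix in this package is: the 96 trinucleotide features
#' sorted by (substitution class, 5' flank, 3' flank), then the 24 five-prime
#' dinucleotide features, then the 24 three-prime ones, then the 6
#' substitution classes.
#'
#' @return A character vector of feature names.
#' @export
#' @examples
#' head(sbs96_contexts())
#' length(context_feature_names())
sbs96_contexts <- function() {
  unlist(lapply(mono_classes(), function(m) {
    as.vector(t(outer(.bases, .bases, function(u, d) {
      paste0(u, "[", m, "]", d)
    })))
  }), use.names = FALSE)
}

#' @rdname sbs96_contexts
#' @export
mono_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' @rdname sbs96_contexts
#' @export
di48_contexts <- function() {
  five <- unlist(lapply(mono_classes(), function(m) paste0(.bases, "[", m, "]")))
  three <- unlist(lapply(mono_classes(), function(m) paste0("[", m, "]", .bases)))
  c(five, three)
}

#' @rdname sbs96_contexts
#' @export
context_feature_names <- function() {
  c(sbs96_contexts(), di48_contexts(), mono_classes())
}

#' Collapse a substitution with flanks onto the pyrimidine strand
#'
#' If the reference base is a purine (A or G), the substitution and its flanks
#' are reverse-complemented, so the returned class always has a C or T
#' reference; the returned 5' flank is then the complement of the input 3'
#' flank and vice versa. All arguments are vectorized and recycled to a common
#' length.
#'
#' @param ref,alt Reference and alternate bases (single characters in ACGT,
#'   `ref != alt`).
#' @param up,down 5' and 3' flanking bases read from the genome.
#' @return A tibble with columns `tri`, `di5`, `di3`, `mono` holding the
#'   canonical labels of the four context features the substitution
#'   increments.
#' @export
#' @examples
#' collapse_substitution("C", "T", "A", "G") # A[C>T]G
#' collapse_substitution("G", "A", "T", "C") # G[C>T]A (collapsed)
collapse_substitution <- function(ref, alt, up, down) {
  n <- max(length(ref), length(alt), length(up), length(down))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  up <- rep_len(up, n); down <- rep_len(down, n)
  ok <- ref %in% .bases & alt %in% .bases & up %in% .bases & down %in% .bases
  if (!all(ok)) {
    stop("collapse_substitution(): bases outside {A,C,G,T} at positions ",
         paste(utils::head(which(!ok), 5L), collapse = ", "))
  }
  if (any(ref == alt)) {
    stop("collapse_substitution(): ref == alt at positions ",
         paste(utils::head(which(ref == alt), 5L), collapse = ", "))
  }
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, .comp[ref], ref)
  a <- ifelse(flip, .comp[alt], alt)
  u <- ifelse(flip, .comp[down], up)
  d <- ifelse(flip, .comp[up], down)
  mono <- paste0(r, ">", a)
  tibble::tibble(
    tri = paste0(u, "[", mono, "]", d),
    di5 = paste0(u, "[", mono, "]"),
    di3 = paste0("[", mono, "]", d),
    mono = mono
  )
}

# Integer base codes with A=1, C=2, G=3, T=4 so that complement(code)=5-code.
.base_code <- function(chars) {
  code <- match(chars, .bases)
  code
}

# Encode one chromosome string as integer codes (NA for non-ACGT).
.seq_codes <- function(seq) {
  ints <- utf8ToInt(seq)
  code <- integer(length(ints))
  code[] <- NA_integer_
  code[ints == 65L] <- 1L  # A
  code[ints == 67L] <- 2L  # C
  code[ints == 71L] <- 3L  # G
  code[ints == 84L] <- 4L  # T
  code
}

# Map each of the 96 trinucleotide classes to:
#   pyr-strand (up, ref, down, alt) codes and its collapsed-trinucleotide key.
# Keys index the 32 pyrimidine-centred reference trinucleotides:
#   key = (ref_is_T)*16 + (up-1)*4 + down, ref in {C,T}.
.sbs96_table <- function() {
  alts <- list(`C>A` = c(2L, 1L), `C>G` = c(2L, 3L), `C>T` = c(2L, 4L),
               `T>A` = c(4L, 1L), `T>C` = c(4L, 2L), `T>G` = c(4L, 3L))
  rows <- lapply(seq_along(mono_classes()), function(mi) {
    ra <- alts[[mono_classes()[mi]]]
    grid <- expand.grid(down = 1:4, up = 1:4)
    grid <- grid[order(grid$up, grid$down), ]
    tibble::tibble(
      class = 16L * (mi - 1L) + seq_len(16L),
      mono = mono_classes()[mi],
      up = as.integer(grid$up), down = as.integer(grid$down),
      ref = ra[1], alt = ra[2]
    )
  })
  out <- dplyr::bind_rows(rows)
  out$tri <- sbs96_contexts()
  out$key <- (out$ref == 4L) * 16L + (out$up - 1L) * 4L + out$down
  out$mono_ref_chr <- .bases[out$ref]
  out$mono_alt_chr <- .bases[out$alt]
  out
}

# Collapsed-trinucleotide key of every interior genomic position, or NA where
# the window contains a non-ACGT base. `codes` is one chromosome's codes.
.position_keys <- function(codes) {
  L <- length(codes)
  if (L < 3L) return(integer(0))
  up <- codes[1:(L - 2L)]
  ce <- codes[2:(L - 1L)]
  dn <- codes[3:L]
  pyr <- ce %in% c(2L, 4L)
  u <- ifelse(pyr, up, 5L - dn)
  c2 <- ifelse(pyr, ce, 5L - ce)
  d <- ifelse(pyr, dn, 5L - up)
  key <- (c2 == 4L) * 16L + (u - 1L) * 4L + d
  key[is.na(up) | is.na(ce) | is.na(dn)] <- NA_integer_
  as.integer(key)
}
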