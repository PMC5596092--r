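.pkg_env <- new.env(parent = emptyenv())

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, case-insensitive).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Round half away from zero
#'
#' Base R rounds half to even; printed report tables use conventional
#' half-up rounding instead (0.275 -> 0.28 at 2 digits).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# map a DNA/RNA string to integer codes 1=A 2=C 3=G 4=U(T); anything else 0
seq_codes <- function(x) {
  v <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  unname(c(A = 1L, C = 2L, G = 3L, T = 4L, U = 4L)[v]) -> out
  out[is.na(out)] <- 0L
  out
}

codes_to_rna <- function(codes) {
  paste(c("A", "C", "G", "U")[codes], collapse = "")
}

# RNA pair type: 1 CG, 2 GC, 3 GU, 4 UG, 5 AU, 6 UA, 0 invalid
pair_type <- function(a, b) {
  ifelse(a == 2L & b == 3L, 1L,
  ifelse(a == 3L & b == 2L, 2L,
  ifelse(a == 3L & b == 4L, 3L,
  ifelse(a == 4L & b == 3L, 4L,
  ifelse(a == 1L & b == 4L, 5L,
  ifelse(a == 4L & b == 1L, 6L, 0L))))))
}

rand_dna <- function(n, gc = 0.6) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
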