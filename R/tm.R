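# Nearest-neighbor duplex melting temperature.
#
# Unified NN thermodynamics (SantaLucia & Hicks 2004 parameter set), duplex
# initiation terms, terminal A/T penalty, and the SantaLucia (1998) entropy
# salt correction. Conditions follow common primer-design practice:
# 25 nM primer and 25 nM template (effective concentration C_T/4), 50 mM
# monovalent cation. The model is strand-symmetric: Tm(seq) == Tm(revcomp).

.NN_BASES <- c("A", "C", "G", "T")

.nn_tables <- local({
  # dH kcal/mol, dS cal/(mol K) for the 10 unique NN steps; the remaining 6
  # follow by reverse-complement symmetry.
  uniq <- rbind(
    AA = c(-7.6, -21.3), AT = c(-7.2, -20.4), TA = c(-7.2, -21.3),
    CA = c(-8.5, -22.7), GT = c(-8.4, -22.4), CT = c(-7.8, -21.0),
    GA = c(-8.2, -22.2), CG = c(-10.6, -27.2), GC = c(-9.8, -24.4),
    GG = c(-8.0, -19.9)
  )
  dh <- ds <- matrix(NA_real_, 4, 4, dimnames = list(.NN_BASES, .NN_BASES))
  # self-contained dinucleotide reverse complement (runs at load time)
  rc <- function(d) {
    b <- rev(strsplit(chartr("ACGT", "TGCA", d), "")[[1]])
    paste(b, collapse = "")
  }
  for (d in rownames(uniq)) {
    b <- strsplit(d, "")[[1]]
    dh[b[1], b[2]] <- uniq[d, 1]; ds[b[1], b[2]] <- uniq[d, 2]
    b2 <- strsplit(rc(d), "")[[1]]
    dh[b2[1], b2[2]] <- uniq[d, 1]; ds[b2[1], b2[2]] <- uniq[d, 2]
  }
  list(dh = dh, ds = ds)
})

# flattened 16-entry lookup indexed by (code1-1)*4+code2, codes A=1..T=4
.NN_DH <- as.vector(t(.nn_tables$dh))
.NN_DS <- as.vector(t(.nn_tables$ds))

.TM_R     <- 1.987        # gas constant, cal/(mol K)
.TM_DNAC  <- 12.5e-9      # (dnac1 - dnac2/2) with 25/25 nM
.TM_NA    <- 0.05         # [Na+] mol/L
.TM_INIT_DH <- 0.2;  .TM_INIT_DS <- -5.7
.TM_AT_DH   <- 2.2;  .TM_AT_DS   <- 6.9

#' Primer melting temperature (nearest-neighbor model)
#'
#' Unified nearest-neighbor thermodynamics with duplex initiation and
#' terminal A/T terms plus an entropy-based salt correction, evaluated at
#' 25 nM primer / 25 nM template and 50 mM Na+. Used by the built-in primer
#' engine to score candidate primers against the 60 degC optimum.
#'
#' @param seq character vector of primer sequences (A/C/G/T, any case).
#' @return numeric vector of melting temperatures in degrees Celsius.
#' @examples
#' melting_temperature("ACGTACGTACGTACGTACGT")
#' @export
melting_temperature <- function(seq) {
  vapply(seq, function(s) {
    code <- match(strsplit(toupper(s), "")[[1]], .NN_BASES)
    n <- length(code)
    if (n < 2 || anyNA(code)) stop("melting_temperature: sequence must be ACGT of length >= 2")
    idx <- (code[-n] - 1L) * 4L + code[-1L]
    dh <- .TM_INIT_DH + sum(.NN_DH[idx]) +
      .TM_AT_DH * ((code[1] %in% c(1L, 4L)) + (code[n] %in% c(1L, 4L)))
    ds <- .TM_INIT_DS + sum(.NN_DS[idx]) +
      .TM_AT_DS * ((code[1] %in% c(1L, 4L)) + (code[n] %in% c(1L, 4L))) +
      0.368 * (n - 1) * log(.TM_NA)
    1000 * dh / (ds + .TM_R * log(.TM_DNAC)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}
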