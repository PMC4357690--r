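# Internal helpers shared across modules.
#
# Coordinate convention: all intervals are 0-based half-open [start, end),
# like BED. CCDS input coordinates (0-based, inclusive end) are converted on
# parse; R's 1-based substr() indices only ever appear inside this file and
# the engine.

#' Reverse complement of a DNA string
#'
#' Case-preserving (soft-masking survives), IUPAC N allowed.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", x)
  # byte-preserving C-level reversal (case survives)
  as.character(Biostrings::reverse(Biostrings::BStringSet(comp)))
}

# substring by 0-based half-open interval
substr0 <- function(x, start, end) {
  if (end <= start) return("")
  substr(x, start + 1L, end)
}

# TRUE where intervals [as,ae) and [bs,be) share >=1 base (vectorised)
ivl_overlaps <- function(as, ae, bs, be) as < be & bs < ae

# stop() unless all named conditions hold; messages name the failing check
check_that <- function(...) {
  conds <- list(...)
  nm <- names(conds)
  for (i in seq_along(conds)) {
    if (!isTRUE(all(conds[[i]]))) stop(nm[i], call. = FALSE)
  }
  invisible(TRUE)
}

# logged note to stderr (structured-ish, quiet under option)
log_note <- function(...) {
  if (!isTRUE(getOption("raavarms.quiet", FALSE))) {
    message("[raavarms] ", ...)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
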