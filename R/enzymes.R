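#' Anchoring enzymes used in SAGE library construction
#'
#' SAGE tags are defined by the 3'-most recognition site of an "anchoring"
#' restriction enzyme on the transcript: the tag is the ten nucleotides
#' immediately downstream (3') of that site. NlaIII (site CATG) is by far the
#' most common anchoring enzyme; Sau3AI (GATC) and RsaI (GTAC) are the second
#' and third most common alternatives.
#'
#' @param name Enzyme name, one of `"NlaIII"`, `"Sau3AI"`, `"RsaI"`
#'   (case-insensitive).
#' @return An object of class `anchoring_enzyme`: a list with elements
#'   `name`, `site` (the 4-nt recognition sequence) and `tag_length`
#'   (10 nt for conventional SAGE).
#' @examples
#' anchoring_enzyme("NlaIII")
#' @export
anchoring_enzyme <- function(name = c("NlaIII", "Sau3AI", "RsaI")) {
  sites <- c(nlaiii = "CATG", sau3ai = "GATC", rsai = "GTAC")
  canon <- c(nlaiii = "NlaIII", sau3ai = "Sau3AI", rsai = "RsaI")
  key <- tolower(if (is.character(name)) name[1] else stop("name must be character"))
  if (!key %in% names(sites)) {
    stop("unknown anchoring enzyme: ", name[1],
         " (supported: NlaIII, Sau3AI, RsaI)")
  }
  structure(
    list(name = canon[[key]], site = sites[[key]], tag_length = 10L),
    class = "anchoring_enzyme"
  )
}

#' @export
print.anchoring_enzyme <- function(x, ...) {
  cat(sprintf("<anchoring enzyme %s: site %s, tag length %d nt>\n",
              x$name, x$site, x$tag_length))
  invisible(x)
}

as_enzyme <- function(enzyme) {
  if (inherits(enzyme, "anchoring_enzyme")) enzyme else anchoring_enzyme(enzyme)
}

# The noninformative tag produced by oligo(dT)-primed poly-A tails.
POLYA_TAG <- "AAAAAAAAAA"
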