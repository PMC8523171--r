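#' Repeat nucleic-acid lattice
#'
#' A repeat nucleic-acid target (e.g. a GU- or GT-repeat tract) described by
#' its length and by the footprint/spacer geometry of the protein monomers
#' that bind it: each monomer occupies `footprint_nt` consecutive nucleotides
#' and leaves `spacer_nt` free nucleotides before the next monomer can start.
#' The defaults (9 nt footprint, 1 nt spacer) describe a tandem-RRM monomer
#' on a GU repeat, where the first monomer covers G1..G9, position 10 stays
#' free, and the next monomer starts at position 11.
#'
#' @param length_nt Lattice length in nucleotides (>= 0).
#' @param footprint_nt Nucleotides occupied per bound monomer (>= 1).
#' @param spacer_nt Free nucleotides between consecutive monomers (>= 0).
#' @param sequence_label Free-text label, e.g. `"(GU)12"`.
#'
#' @return An object of class `"repeat_lattice"`.
#' @examples
#' repeat_lattice(24, sequence_label = "(GU)12")
#' @export
repeat_lattice <- function(length_nt, footprint_nt = 9L, spacer_nt = 1L,
                           sequence_label = "") {
  if (!is.numeric(length_nt) || length(length_nt) != 1L || is.na(length_nt) ||
      length_nt < 0 || length_nt != floor(length_nt)) {
    stop("`length_nt` must be a single non-negative integer", call. = FALSE)
  }
  if (!is.numeric(footprint_nt) || footprint_nt < 1 ||
      footprint_nt != floor(footprint_nt)) {
    stop("`footprint_nt` must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(spacer_nt) || spacer_nt < 0 || spacer_nt != floor(spacer_nt)) {
    stop("`spacer_nt` must be an integer >= 0", call. = FALSE)
  }
  structure(
    list(length_nt = as.integer(length_nt),
         footprint_nt = as.integer(footprint_nt),
         spacer_nt = as.integer(spacer_nt),
         sequence_label = as.character(sequence_label)),
    class = "repeat_lattice"
  )
}

#' @export
print.repeat_lattice <- function(x, ...) {
  lab <- if (nzchar(x$sequence_label)) paste0(" [", x$sequence_label, "]") else ""
  cat(sprintf("<repeat_lattice>%s %d nt, footprint %d nt, spacer %d nt, up to %d monomer(s)\n",
              lab, x$length_nt, x$footprint_nt, x$spacer_nt, max_stoichiometry(x)))
  invisible(x)
}

#' Maximal number of monomers a lattice can accommodate
#'
#' With footprint `f` and spacer `s`, `k` monomers need `k*f + (k-1)*s`
#' nucleotides, so the maximum is `floor((length + s) / (f + s))`.
#' A 48-nt (GT)24 tract takes up to four 9+1 monomers, 24 nt takes two,
#' 12 nt takes one and anything shorter than the footprint takes none.
#'
#' @param lattice A [repeat_lattice()].
#' @return Integer monomer count (possibly 0).
#' @examples
#' max_stoichiometry(repeat_lattice(48)) # 4
#' max_stoichiometry(repeat_lattice(12)) # 1
#' @export
max_stoichiometry <- function(lattice) {
  stopifnot(inherits(lattice, "repeat_lattice"))
  f <- lattice$footprint_nt
  s <- lattice$spacer_nt
  n <- (lattice$length_nt + s) %/% (f + s)
  as.integer(max(n, 0L))
}

#' Binding registers along a repeat lattice
#'
#' Positions of each bound monomer when monomers pack 5' to 3' from position
#' 1, each occupying `footprint_nt` nucleotides and skipping `spacer_nt`
#' before the next. Coordinates are 1-based and inclusive, so on a 24-nt
#' (GU)12 lattice the two registers are (1, 9) and (11, 19): the first
#' monomer covers G1..G9, position 10 stays free and the second monomer
#' covers G11..G19.
#'
#' @param lattice A [repeat_lattice()].
#' @return A data frame with columns `register`, `start_nt`, `end_nt`
#'   (one row per monomer, `max_stoichiometry(lattice)` rows).
#' @examples
#' place_registers(repeat_lattice(24))
#' @export
place_registers <- function(lattice) {
  stopifnot(inherits(lattice, "repeat_lattice"))
  n <- max_stoichiometry(lattice)
  period <- lattice$footprint_nt + lattice$spacer_nt
  k <- seq_len(n)
  data.frame(
    register = k,
    start_nt = 1L + (k - 1L) * period,
    end_nt   = lattice$footprint_nt + (k - 1L) * period
  )
}
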