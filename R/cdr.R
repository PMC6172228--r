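# CDR definitions follow the IMGT boundaries expressed in AHo coordinates.
# In the combined VHVL numbering the VL occupies positions 150-298, so the
# printed VL ranges are shifted by -149 for a standalone VL alignment.

.CDR_RANGES <- list(
  VH   = list(CDR1 = c(27L, 40L),  CDR2 = c(58L, 68L),  CDR3 = c(107L, 138L)),
  VL   = list(CDR1 = c(27L, 40L),  CDR2 = c(58L, 68L),  CDR3 = c(108L, 138L)),
  VHVL = list(`VH-CDR1` = c(27L, 40L),   `VH-CDR2` = c(58L, 68L),
              `VH-CDR3` = c(107L, 138L), `VL-CDR1` = c(176L, 189L),
              `VL-CDR2` = c(207L, 217L), `VL-CDR3` = c(257L, 287L))
)

#' CDR position mask for a chain
#'
#' Returns the set of 1-based alignment positions belonging to the
#' Complementarity-Determining Regions under the IMGT boundary convention
#' in AHo coordinates: VH 27-40, 58-68, 107-138; in the combined VHVL
#' numbering the VL CDRs are 176-189, 207-217, 257-287. These positions
#' are held fixed during humanization and can be excluded from
#' framework-only distance scores.
#'
#' @param chain One of `"VH"`, `"VL"`, `"VHVL"`.
#' @return An object of class `cdr_mask` with fields `positions` (sorted
#'   integer vector), `chain` and `scheme`.
#' @export
#' @examples
#' length(cdr_mask("VH")$positions)    # 57
#' length(cdr_mask("VHVL")$positions)  # 113
cdr_mask <- function(chain = c("VH", "VL", "VHVL")) {
  chain <- match.arg(chain)
  rg <- .CDR_RANGES[[chain]]
  pos <- sort(unique(unlist(lapply(rg, function(r) seq(r[1], r[2])))))
  structure(list(positions = as.integer(pos), chain = chain,
                 scheme = "IMGT-AHo"),
            class = "cdr_mask")
}

#' @export
print.cdr_mask <- function(x, ...) {
  cat(sprintf("<cdr_mask> %s (%s), %d positions\n",
              x$chain, x$scheme, length(x$positions)))
  invisible(x)
}

#' @export
as_tibble.cdr_mask <- function(x, ...) {
  rg <- .CDR_RANGES[[x$chain]]
  tibble(
    start = vapply(rg, `[`, integer(1), 1),
    end = vapply(rg, `[`, integer(1), 2),
    name = names(rg)
  )
}

#' Export a CDR mask to TSV or JSON
#'
#' TSV output is BED-like (columns start, end, name; 1-based inclusive).
#'
#' @param mask A `cdr_mask`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_cdr_mask <- function(mask, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- as_tibble(mask)
  if (format == "tsv") {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(chain = mask$chain, scheme = mask$scheme, regions = tab,
           positions = mask$positions),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# normalize a mask argument (cdr_mask object, integer vector, or NULL)
mask_positions <- function(mask, L) {
  if (is.null(mask)) return(integer(0))
  pos <- if (inherits(mask, "cdr_mask")) mask$positions else as.integer(mask)
  if (anyDuplicated(pos)) abort("mask positions must be unique")
  if (length(pos) > 0 && (min(pos) < 1 || max(pos) > L))
    abort(sprintf("mask positions must lie in [1, %d]", L))
  sort(pos)
}
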