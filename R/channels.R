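# Scalp geometry derived algorithmically from 10-5 electrode names.

# Anterior-to-posterior row codes of the extended 10-5 scheme; y decreases
# from front (Fp) to back (I), with the central row C at y = 0.
.chan_rows <- c("Fp", "AFp", "AF", "AFF", "F", "FFC", "FC", "FCC", "C",
                "CCP", "CP", "CPP", "P", "PPO", "PO", "POO", "O", "OI", "I")

#' Nominal 2-D positions for 10-5 electrode labels
#'
#' Parses extended 10-5 labels (e.g. `C3`, `FCC1h`, `CPz`, `AFp2`) into
#' nominal planar coordinates used for spatial modelling: `x` grows to the
#' right (odd digits are left-hemisphere, even right, `z` midline; an `h`
#' suffix marks half-distance positions), `y` grows to the front with the
#' central row at `y = 0`. Units are inter-electrode steps of the 10-20
#' grid, not centimetres; only relative geometry is meaningful.
#'
#' Labels that are not 10-5 names (e.g. EMG channels) get `NA` coordinates.
#'
#' @param labels character vector of channel labels.
#' @return data.frame with columns `label`, `x`, `y`, `hemisphere`
#'   (`"left"`, `"right"`, `"midline"` or `NA`).
#' @examples
#' channel_positions(c("C1", "C2", "CPz", "FCC3h", "EMGl"))
#' @export
channel_positions <- function(labels) {
  m <- regmatches(labels, regexec("^([A-Za-z]+?)(z|[0-9]+)(h?)$", labels))
  one <- function(label, parts) {
    if (length(parts) == 0L || !(parts[2] %in% .chan_rows)) {
      return(data.frame(label = label, x = NA_real_, y = NA_real_,
                        hemisphere = NA_character_))
    }
    y <- (9L - match(parts[2], .chan_rows)) * 0.5
    if (parts[3] == "z") {
      x <- 0; hemi <- "midline"
    } else {
      d <- as.integer(parts[3])
      x <- ceiling(d / 2) - if (nzchar(parts[4])) 0.5 else 0
      if (d %% 2 == 1L) { x <- -x; hemi <- "left" } else hemi <- "right"
    }
    data.frame(label = label, x = x, y = y, hemisphere = hemi)
  }
  out <- do.call(rbind, Map(one, labels, m))
  rownames(out) <- NULL
  out
}

#' Recommended 32-channel montage
#'
#' A sensorimotor-centred 10-5 channel subset (32 channels) plus the `CPz`
#' reference, shipped as an editable text file in
#' `inst/extdata/montage_32.txt`. This is a synthetic stand-in list chosen
#' to cover the hand-knob region densely; edit the file to match a lab's
#' preferred montage.
#'
#' @param file optional path to an alternative montage file. The format is
#'   one label per line; the line marked with a trailing `*` is the
#'   reference.
#' @return list with `channels` (character, 32 labels) and `reference`
#'   (single label).
#' @export
default_montage <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "montage_32.txt", package = "premove")
  }
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ref <- sub("\\s*\\*$", "", lines[grepl("\\*$", lines)])
  chans <- lines[!grepl("\\*$", lines)]
  if (length(ref) != 1L) stop("montage file must mark exactly one reference with '*'")
  list(channels = chans, reference = ref)
}

# Evaluate and restore the global RNG state around seeded simulation code so
# generators are bitwise reproducible without clobbering the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
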