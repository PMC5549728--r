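# Residue-numbering conventions for the hyaluronan chain.
#
# HA is the alternating copolymer [-GlcUA-GlcNAc-]; the reducing end is the
# GlcNAc terminus. Disaccharide units are numbered so that the disaccharide
# closest to the key binding residue (R41 by default) carries index 0,
# indices decrease toward the reducing end and increase toward the
# non-reducing (GlcUA) terminus.

GLCUA_NAMES  <- c("GCU", "GCA", "UAP", "GLCUA", "GlcUA")
GLCNAC_NAMES <- c("NAG", "NDG", "GLCNAC", "GlcNAc")

mono_type <- function(resname) {
  ifelse(resname %in% GLCUA_NAMES, "GlcUA",
         ifelse(resname %in% GLCNAC_NAMES, "GlcNAc", NA_character_))
}

#' Assign signed disaccharide numbering to the HA chain
#'
#' The disaccharide whose minimum heavy-atom distance to the key residue is
#' smallest receives index 0; a tie (within `tie_tol`) is resolved toward the
#' reducing end. Numbering follows the chemistry (reducing = GlcNAc
#' terminus), not the file order, and is invariant to rigid-body motion.
#'
#' @param model a `habind_structure` containing a protein and a polymer chain.
#' @param coords `atoms x 3` coordinate matrix (nm) of the frame used for the
#'   distance criterion; defaults to the model coordinates.
#' @param key_residue canonical residue number of the key binding site
#'   (default 41).
#' @param tie_tol distances within this of the minimum count as ties (nm).
#' @return a `habind_residue_map`: data.frame with `resno`, `resname`,
#'   `mono` (GlcUA/GlcNAc), `mono_pos` (1-based from the reducing end) and
#'   `disaccharide` (signed index), plus attributes `key_residue` and
#'   `file_order_reducing_first`.
#' @export
assign_ha_numbering <- function(model, coords = NULL, key_residue = 41L,
                                tie_tol = 0) {
  stopifnot(inherits(model, "habind_structure"))
  if (is.null(coords)) coords <- model$xyz
  a <- model$atoms
  poly_chains <- names(model$roles)[model$roles == "polymer"]
  if (!length(poly_chains)) stop("model has no chain tagged 'polymer'")
  pa <- a[a$chain %in% poly_chains, ]
  res <- unique(pa[, c("chain", "resno", "resname")])
  res <- res[order(match(paste(res$chain, res$resno),
                         unique(paste(pa$chain, pa$resno)))), ]
  res$mono <- mono_type(res$resname)
  if (anyNA(res$mono))
    stop("polymer composition error: unknown monosaccharide name(s): ",
         paste(unique(res$resname[is.na(res$mono)]), collapse = ", "))
  n <- nrow(res)
  if (n %% 2 != 0)
    stop("polymer composition error: odd monosaccharide count (", n, ")")
  if (any(res$mono[-1] == res$mono[-n]))
    stop("polymer composition error: chain is not alternating GlcUA/GlcNAc")
  # reducing end = GlcNAc terminus
  reducing_first <- res$mono[1] == "GlcNAc"
  ord <- if (reducing_first) seq_len(n) else rev(seq_len(n))
  res <- res[ord, ]
  res$mono_pos <- seq_len(n)
  res$dis_pos <- (res$mono_pos + 1L) %/% 2L  # 1-based disaccharide from reducing end

  prot_chains <- names(model$roles)[model$roles == "protein"]
  heavy <- is_heavy(model)
  key_idx <- which(a$chain %in% prot_chains & a$resno == key_residue & heavy)
  if (!length(key_idx)) stop("key residue ", key_residue, " not found in protein")
  key_xyz <- coords[key_idx, , drop = FALSE]

  ndis <- n %/% 2L
  dmin <- vapply(seq_len(ndis), function(j) {
    rows <- res[res$dis_pos == j, ]
    idx <- which(a$chain %in% poly_chains &
                   paste(a$chain, a$resno) %in% paste(rows$chain, rows$resno) &
                   heavy)
    min_distance(coords[idx, , drop = FALSE], key_xyz)
  }, numeric(1))
  j0 <- which(dmin <= min(dmin) + tie_tol)[1]  # tie -> reducing-end side
  res$disaccharide <- res$dis_pos - j0
  out <- res[, c("resno", "resname", "mono", "mono_pos", "disaccharide")]
  rownames(out) <- NULL
  attr(out, "key_residue") <- as.integer(key_residue)
  attr(out, "file_order_reducing_first") <- reducing_first
  class(out) <- c("habind_residue_map", "data.frame")
  out
}

#' Export a residue map as JSON
#' @param map a `habind_residue_map`.
#' @param path output file.
#' @export
write_residue_map <- function(map, path) {
  jsonlite::write_json(
    list(key_residue = attr(map, "key_residue"),
         file_order_reducing_first = attr(map, "file_order_reducing_first"),
         residues = as.data.frame(unclass(map))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
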