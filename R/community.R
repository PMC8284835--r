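#' Construct a plot-by-species community block
#'
#' One patch's sampled community: an `N` plots by `S` species matrix of
#' individual counts, per-species dispersal-syndrome flags, and the patch
#' centre in planar metres.
#'
#' @param patch_id Patch identifier (character or coercible).
#' @param abundance Non-negative integer matrix, plots in rows, species in
#'   columns.
#' @param species_labels Character vector of `S` species identifiers
#'   (defaults to column names or `sp1..spS`).
#' @param dispersal Logical vector of length `S`; `TRUE` marks
#'   animal-dispersed species.
#' @param centre Numeric (x, y) of the patch centre, metres.
#' @return An object of class `community_block`.
#' @export
community_block <- function(patch_id, abundance, species_labels = NULL,
                            dispersal = NULL, centre = c(NA_real_, NA_real_)) {
  abundance <- as.matrix(abundance)
  if (nrow(abundance) < 1L || ncol(abundance) < 1L)
    stop("abundance must have at least one plot and one species")
  if (anyNA(abundance) || any(abundance < 0))
    stop("abundances must be non-negative")
  if (any(abundance != round(abundance)))
    stop("abundances must be integer counts")
  if (sum(abundance) == 0)
    stop("community block has no individuals")
  S <- ncol(abundance)
  if (is.null(species_labels)) {
    species_labels <- colnames(abundance)
    if (is.null(species_labels)) species_labels <- paste0("sp", seq_len(S))
  }
  if (length(species_labels) != S) stop("species_labels length mismatch")
  if (is.null(dispersal)) dispersal <- rep(TRUE, S)
  if (length(dispersal) != S) stop("dispersal length mismatch")
  storage.mode(abundance) <- "integer"
  colnames(abundance) <- species_labels
  rownames(abundance) <- paste0("plot", seq_len(nrow(abundance)))
  structure(
    list(patch_id = as.character(patch_id), abundance = abundance,
         species_labels = as.character(species_labels),
         dispersal = as.logical(dispersal), centre = as.numeric(centre)),
    class = "community_block"
  )
}

#' @export
print.community_block <- function(x, ...) {
  cat(sprintf(
    "community_block %s: %d plots x %d species, %d individuals (%.1f%% animal-dispersed species)\n",
    x$patch_id, nrow(x$abundance), ncol(x$abundance), sum(x$abundance),
    100 * mean(x$dispersal)))
  invisible(x)
}

#' Restrict a community block to animal-dispersed species
#'
#' Drops all species not flagged animal-dispersed; the number of plots is
#' unchanged. Analyses of animal-dispersed seedlings run on the filtered
#' block.
#'
#' @param block A `community_block`.
#' @return A `community_block` with only the flagged species columns.
#' @export
filter_animal_dispersed <- function(block) {
  stopifnot(inherits(block, "community_block"))
  keep <- which(block$dispersal)
  if (length(keep) == 0L)
    stop("no animal-dispersed species in block ", block$patch_id)
  sub <- block$abundance[, keep, drop = FALSE]
  if (sum(sub) == 0)
    stop("animal-dispersed community is empty in block ", block$patch_id)
  community_block(block$patch_id, sub,
                  species_labels = block$species_labels[keep],
                  dispersal = rep(TRUE, length(keep)),
                  centre = block$centre)
}

#' Write community blocks as a long-format CSV
#'
#' Columns: patch_id, plot, species, abundance, dispersal. Zero cells are
#' omitted; plots that would vanish entirely keep their presence through the
#' plot index of retained rows (every plot holds at least one individual by
#' construction).
#'
#' @param blocks A list of `community_block`s (or a single block).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_community_csv <- function(blocks, path) {
  if (inherits(blocks, "community_block")) blocks <- list(blocks)
  rows <- lapply(blocks, function(b) {
    idx <- which(b$abundance > 0, arr.ind = TRUE)
    data.frame(
      patch_id = b$patch_id,
      plot = idx[, 1],
      species = b$species_labels[idx[, 2]],
      abundance = b$abundance[idx],
      dispersal = b$dispersal[idx[, 2]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$patch_id, out$plot, out$species), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read community blocks from a long-format CSV
#'
#' Inverse of [write_community_csv()]. Plot indices absent from the file for
#' a patch (possible only for files not written by this package) raise an
#' error, since empty plots make plot-level diversity undefined.
#'
#' @param path CSV path with columns patch_id, plot, species, abundance,
#'   dispersal.
#' @param centres Optional data.frame (patch_id, x, y) of patch centres.
#' @return Named list of `community_block`s.
#' @export
read_community_csv <- function(path, centres = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patch_id", "plot", "species", "abundance", "dispersal")
  if (!all(need %in% names(df))) stop("community CSV missing columns")
  blocks <- lapply(split(df, df$patch_id), function(d) {
    plots <- sort(unique(d$plot))
    if (!identical(plots, seq_len(max(plots))))
      stop("patch ", d$patch_id[1], " has empty plots in CSV")
    species <- sort(unique(d$species))
    A <- matrix(0L, nrow = max(plots), ncol = length(species),
                dimnames = list(NULL, species))
    A[cbind(d$plot, match(d$species, species))] <- as.integer(d$abundance)
    disp <- vapply(split(d$dispersal, d$species), function(z) as.logical(z[1]),
                   logical(1))[species]
    ctr <- c(NA_real_, NA_real_)
    if (!is.null(centres)) {
      hit <- match(d$patch_id[1], centres$patch_id)
      if (!is.na(hit)) ctr <- c(centres$x[hit], centres$y[hit])
    }
    community_block(d$patch_id[1], A, species_labels = species,
                    dispersal = disp, centre = ctr)
  })
  blocks[order(names(blocks))]
}
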