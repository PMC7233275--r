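#' Read a plate run (amplification + melt curves) with well metadata
#'
#' Reads the long-format plate file and the per-well metadata file and
#' returns one row per well with nested amplification and melt curves.
#' The plate file is delimited text (comma or tab) with columns
#' `plate_id, well_id, stage, x, fluorescence`, where `stage` is `"AMP"`
#' (then `x` is the PCR cycle) or `"MELT"` (then `x` is temperature in
#' degrees Celsius). The metadata file has columns
#' `plate_id, well_id, sample_id, population_id, replicate_index,
#' known_haplotype` (the last two may be blank).
#'
#' Melt curves must have strictly increasing temperatures on a uniform
#' grid (default instrument protocol: 65-95 degrees C in 0.2 degree
#' steps). Wells present in the metadata but lacking melt data are
#' dropped and reported in the `"rejected"` attribute of the result.
#'
#' @param path plate file path.
#' @param metadata_path metadata file path.
#' @return A tibble with one row per well: the metadata columns plus
#'   list-columns `amplification` (tibble `cycle`, `fluorescence`) and
#'   `melt` (tibble `temperature`, `fluorescence`). Attribute
#'   `"rejected"` holds a tibble of wells dropped with a reason.
#' @export
read_plate <- function(path, metadata_path) {
  # numeric columns come in as text and go through base R's correctly
  # rounded strtod, so values survive a write/read round trip exactly
  raw <- read_plate_file(path, c("plate_id", "well_id", "stage", "x", "fluorescence"),
                         readr::cols(plate_id = "c", well_id = "c", stage = "c",
                                     x = "c", fluorescence = "c"))
  for (col in c("x", "fluorescence")) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("%s: malformed numeric '%s' in column %s at row %d",
                    path, raw[[col]][bad[1]], col, bad[1]))
    }
    raw[[col]] <- parsed
  }
  meta <- read_plate_file(metadata_path,
                          c("plate_id", "well_id", "sample_id", "population_id",
                            "replicate_index", "known_haplotype"),
                          readr::cols(plate_id = "c", well_id = "c", sample_id = "c",
                                      population_id = "c", replicate_index = "i",
                                      known_haplotype = "c"))
  if (anyDuplicated(meta[c("plate_id", "well_id")]) > 0) {
    dup <- meta[duplicated(meta[c("plate_id", "well_id")]), ]
    abort(sprintf("duplicate (plate_id, well_id) in metadata: %s/%s",
                  dup$plate_id[1], dup$well_id[1]))
  }
  bad_stage <- setdiff(unique(raw$stage), c("AMP", "MELT"))
  if (length(bad_stage) > 0) {
    abort(sprintf("unknown stage value(s): %s", paste(bad_stage, collapse = ", ")))
  }

  curves <- raw |>
    tidyr::nest(curve = c("x", "fluorescence")) |>
    tidyr::pivot_wider(names_from = "stage", values_from = "curve")
  if (!"AMP" %in% names(curves)) curves$AMP <- list(NULL)
  if (!"MELT" %in% names(curves)) curves$MELT <- list(NULL)

  out <- dplyr::left_join(meta, curves, by = c("plate_id", "well_id"))
  reject <- character(nrow(out))
  for (i in seq_len(nrow(out))) {
    m <- out$MELT[[i]]
    if (is.null(m) || nrow(m) == 0) {
      reject[i] <- "no melt data"
      next
    }
    reject[i] <- validate_melt_grid(m$x)
  }
  rejected <- out[reject != "", c("plate_id", "well_id", "sample_id")]
  rejected$reason <- reject[reject != ""]
  hard <- grepl("temperature", rejected$reason)
  if (any(hard)) {
    abort(sprintf("well %s/%s: %s", rejected$plate_id[hard][1],
                  rejected$well_id[hard][1], rejected$reason[hard][1]))
  }
  out <- out[reject == "", ]
  out$amplification <- lapply(out$AMP, function(a) {
    if (is.null(a)) return(NULL)
    if (is.unsorted(a$x, strictly = TRUE)) abort("amplification cycles not strictly increasing")
    tibble(cycle = as.integer(a$x), fluorescence = a$fluorescence)
  })
  out$melt <- lapply(out$MELT, function(m) {
    tibble(temperature = m$x, fluorescence = m$fluorescence)
  })
  out$AMP <- out$MELT <- NULL
  out <- as_tibble(out)
  attr(out, "rejected") <- as_tibble(rejected)
  if (nrow(rejected) > 0) {
    warn(sprintf("%d well(s) rejected (no melt data); see attr(x, 'rejected')",
                 nrow(rejected)))
  }
  out
}

read_plate_file <- function(path, expected, col_types) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  x <- readr::read_delim(path, delim = delim, col_types = col_types,
                         na = c("", "NA"), progress = FALSE)
  missing <- setdiff(expected, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")))
  }
  prob <- readr::problems(x)
  if (nrow(prob) > 0) {
    abort(sprintf("%s: malformed field at row %d (%s)", path, prob$row[1],
                  prob$expected[1]))
  }
  x
}

# "" if ok, otherwise the reason
validate_melt_grid <- function(temps, tol = 1e-6) {
  if (length(temps) < 5) return("melt curve too short")
  d <- diff(temps)
  if (any(d <= 0)) return("melt temperatures not strictly increasing")
  if (max(d) - min(d) > tol) return("melt temperature step not uniform")
  if (min(temps) < 65 - tol || max(temps) > 95 + tol) {
    return("melt temperature range outside protocol window [65, 95]")
  }
  ""
}

#' Write a plate run back to the long plate + metadata format
#'
#' Inverse of [read_plate()]; a write/read round trip reproduces all well
#' metadata and curve values exactly.
#'
#' @param wells tibble as returned by [read_plate()] (or the simulator).
#' @param path,metadata_path output file paths (tab-delimited).
#' @return `wells`, invisibly.
#' @export
write_plate <- function(wells, path, metadata_path) {
  long <- purrr::map_dfr(seq_len(nrow(wells)), function(i) {
    amp <- wells$amplification[[i]]
    melt <- wells$melt[[i]]
    dplyr::bind_rows(
      if (!is.null(amp)) {
        tibble(plate_id = wells$plate_id[i], well_id = wells$well_id[i],
               stage = "AMP", x = as.numeric(amp$cycle),
               fluorescence = amp$fluorescence)
      },
      if (!is.null(melt)) {
        tibble(plate_id = wells$plate_id[i], well_id = wells$well_id[i],
               stage = "MELT", x = melt$temperature,
               fluorescence = melt$fluorescence)
      })
  })
  # serialise doubles at full precision so a write/read round trip is
  # bit-identical
  long$x <- sprintf("%.17g", long$x)
  long$fluorescence <- sprintf("%.17g", long$fluorescence)
  readr::write_tsv(long, path)
  meta_cols <- c("plate_id", "well_id", "sample_id", "population_id",
                 "replicate_index", "known_haplotype")
  meta <- wells[intersect(meta_cols, names(wells))]
  for (mc in setdiff(meta_cols, names(meta))) meta[[mc]] <- NA
  readr::write_tsv(meta[meta_cols], metadata_path)
  invisible(wells)
}
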