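# Landmark tables -------------------------------------------------------
#
# A landmark table is a tibble with one row per digitized point and columns
# specimen_id, taxon, digit, clade, side, landmark, role, x, y. The sliding
# scheme (which semi-landmarks slide between which neighbours) travels with
# the table as the "sliders" attribute, a tibble of (before, slide, after)
# landmark indices. All specimens in one table share the landmark scheme.

DIGITS <- c("I", "II", "III", "unassigned")
CLADES <- c("troodontine", "non_troodontine", "undecided")
SIDES <- c("left", "right")

#' Default claw landmark scheme
#'
#' The 16-point scheme used throughout the package: four fixed anatomical
#' landmarks and twelve sliding semi-landmarks on the dorsal and ventral
#' outline curves of an ungual phalanx in lateral view.
#'
#' Fixed landmarks: 1 dorsoproximal corner of the articular facet,
#' 2 ventroproximal corner (the fulcrum of the lever model), 3 apex of the
#' flexor tubercle, 4 distal tip (the resistance point). Semi-landmarks
#' 5-10 lie on the dorsal curve between landmarks 1 and 4; 11-13 on the
#' ventral curve between the fulcrum and the tubercle apex; 14-16 between
#' the tubercle apex and the tip.
#'
#' @return A list with elements `n` (16), `roles` (character vector of
#'   `"fixed"`/`"sliding"`), and `sliders` (tibble with columns `before`,
#'   `slide`, `after` giving, for each semi-landmark, its two neighbours
#'   along the outline curve).
#' @export
#' @examples
#' claw_landmark_scheme()$sliders
claw_landmark_scheme <- function() {
  roles <- c(rep("fixed", 4), rep("sliding", 12))
  dorsal <- c(1L, 5L, 6L, 7L, 8L, 9L, 10L, 4L)
  ventral <- c(2L, 11L, 12L, 13L, 3L, 14L, 15L, 16L, 4L)
  chain_triples <- function(chain, semis) {
    idx <- match(semis, chain)
    tibble(
      before = chain[idx - 1L],
      slide = semis,
      after = chain[idx + 1L]
    )
  }
  sliders <- dplyr::bind_rows(
    chain_triples(dorsal, 5:10),
    chain_triples(ventral, c(11:13, 14:16))
  )
  list(n = 16L, roles = roles, sliders = sliders)
}

new_landmark_tbl <- function(df, sliders, provenance = NULL) {
  out <- as_tibble(df)
  attr(out, "sliders") <- as_tibble(sliders)
  if (!is.null(provenance)) attr(out, "provenance") <- as_tibble(provenance)
  class(out) <- c("landmark_tbl", class(tibble()))
  out
}

#' Assemble and validate a landmark table
#'
#' @param df Data frame with columns `specimen_id`, `landmark`, `role`, `x`,
#'   `y` and optionally `taxon`, `digit`, `clade`, `side` (missing metadata
#'   columns are filled with defaults).
#' @param sliders Tibble of `(before, slide, after)` landmark indices
#'   defining which semi-landmarks slide between which neighbours; defaults
#'   to the scheme of [claw_landmark_scheme()] when the table matches it.
#'
#' @return A `landmark_tbl` tibble (one row per landmark) carrying the
#'   sliding scheme as the `"sliders"` attribute.
#' @export
landmark_table <- function(df, sliders = NULL) {
  df <- as_tibble(df)
  needed <- c("specimen_id", "landmark", "role", "x", "y")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("landmark table is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"taxon" %in% names(df)) df$taxon <- df$specimen_id
  if (!"digit" %in% names(df)) df$digit <- "unassigned"
  if (!"clade" %in% names(df)) df$clade <- "undecided"
  if (!"side" %in% names(df)) df$side <- "left"
  df$landmark <- as.integer(df$landmark)
  df <- df[, c("specimen_id", "taxon", "digit", "clade", "side", "landmark", "role", "x", "y")]
  if (is.null(sliders)) sliders <- claw_landmark_scheme()$sliders
  out <- new_landmark_tbl(df, sliders)
  validate_landmark_tbl(out)
  out
}

validate_landmark_tbl <- function(x) {
  if (!all(x$role %in% c("fixed", "sliding"))) {
    abort("landmark roles must be 'fixed' or 'sliding'")
  }
  if (!all(x$digit %in% DIGITS)) abort("digit must be one of I, II, III, unassigned")
  if (!all(x$clade %in% CLADES)) abort("clade must be troodontine, non_troodontine or undecided")
  if (!all(x$side %in% SIDES)) abort("side must be left or right")
  if (any(!is.finite(x$x)) || any(!is.finite(x$y))) {
    bad <- unique(x$specimen_id[!is.finite(x$x) | !is.finite(x$y)])
    abort(paste0("non-finite coordinates for specimen(s): ", paste(bad, collapse = ", ")))
  }
  counts <- dplyr::count(x, .data$specimen_id)
  if (length(unique(counts$n)) > 1) {
    abort("all specimens must have the same number of landmarks")
  }
  role_pat <- dplyr::summarise(
    dplyr::group_by(x[order(x$specimen_id, x$landmark), ], .data$specimen_id),
    pat = paste(.data$role, collapse = ","), .groups = "drop"
  )
  if (length(unique(role_pat$pat)) > 1) {
    abort("all specimens must share the same fixed/sliding role pattern")
  }
  sliders <- attr(x, "sliders")
  one <- x[x$specimen_id == x$specimen_id[1], ]
  one <- one[order(one$landmark), ]
  semis <- one$landmark[one$role == "sliding"]
  if (!setequal(sliders$slide, semis)) {
    abort("sliders table must list every sliding semi-landmark exactly once")
  }
  if (anyDuplicated(sliders$slide) > 0) {
    abort("each semi-landmark may belong to exactly one curve segment")
  }
  invisible(x)
}

#' @export
print.landmark_tbl <- function(x, ...) {
  n_spec <- length(unique(x$specimen_id))
  n_lm <- nrow(x) / max(n_spec, 1)
  cat(sprintf(
    "# Landmark table: %d specimen(s), %d landmarks each (%d fixed, %d sliding)\n",
    n_spec, n_lm,
    sum(x$role == "fixed") / max(n_spec, 1),
    sum(x$role == "sliding") / max(n_spec, 1)
  ))
  NextMethod()
}

# split a landmark table into a named list of k x 2 coordinate matrices,
# rows ordered by landmark index
lm_split <- function(x) {
  x <- x[order(x$specimen_id, x$landmark), ]
  ids <- unique(x$specimen_id)
  lapply(setNames(ids, ids), function(id) {
    sub <- x[x$specimen_id == id, ]
    m <- cbind(sub$x, sub$y)
    rownames(m) <- sub$landmark
    m
  })
}

# per-specimen metadata (one row each)
lm_meta <- function(x) {
  dplyr::distinct(
    as_tibble(x)[, c("specimen_id", "taxon", "digit", "clade", "side")]
  )
}

# role vector of the shared scheme, ordered by landmark index
lm_roles <- function(x) {
  one <- x[x$specimen_id == x$specimen_id[1], ]
  one$role[order(one$landmark)]
}

# Reading and writing ----------------------------------------------------

#' Read landmark configurations from a TPS or CSV file
#'
#' TPS files are blocks of `LM=k` followed by `k` whitespace-separated
#' coordinate pairs and optional `ID=`, `IMAGE=`, `SCALE=` lines;
#' coordinates are multiplied by `SCALE` when present, and the y axis is
#' taken as increasing upward (`flip_y = TRUE` negates y for image-origin
#' files). CSV files have one row per landmark with columns `specimen_id`,
#' `landmark`, `role`, `x`, `y` and optional metadata columns. Landmark
#' indices are 1-based in files.
#'
#' Right-side specimens (CSV `side == "right"`) are mirrored to left-lateral
#' orientation on reading (x negated about the centroid) so that all
#' configurations share handedness; the mirroring is recorded in the
#' `"provenance"` attribute.
#'
#' @param path File to read.
#' @param format `"tps"` or `"csv"`; `"auto"` guesses from the extension.
#' @param sliders Sliding scheme as a `(before, slide, after)` tibble, a path
#'   to a sliders CSV with those columns, or `NULL` for the default claw
#'   scheme of [claw_landmark_scheme()] (used when the file has 16 landmarks
#'   and no role column; TPS files always take their roles from `sliders`).
#' @param flip_y Negate y on input (TPS digitized in image coordinates).
#' @param metadata Optional data frame keyed by `specimen_id` supplying
#'   `taxon`, `digit`, `clade` and/or `side` for formats (TPS) that cannot
#'   carry them; matching columns override the defaults.
#'
#' @return A `landmark_tbl`.
#' @export
read_landmarks <- function(path, format = c("auto", "tps", "csv"),
                           sliders = NULL, flip_y = FALSE, metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv"
  }
  sliders <- resolve_sliders(sliders)
  tbl <- switch(format,
    tps = read_landmarks_tps(path, sliders, flip_y),
    csv = read_landmarks_csv(path, sliders, flip_y)
  )
  if (!is.null(metadata)) {
    metadata <- as_tibble(metadata)
    for (col in intersect(c("taxon", "digit", "clade", "side"), names(metadata))) {
      hit <- match(tbl$specimen_id, metadata$specimen_id)
      tbl[[col]] <- ifelse(is.na(hit), tbl[[col]], metadata[[col]][hit])
    }
    validate_landmark_tbl(tbl)
    right <- lm_meta(tbl)$specimen_id[lm_meta(tbl)$side == "right"]
    if (length(right) > 0) tbl <- mirror_landmarks(tbl, specimens = right)
  }
  tbl
}

resolve_sliders <- function(sliders) {
  if (is.null(sliders)) return(claw_landmark_scheme()$sliders)
  if (is.character(sliders)) {
    df <- read.table(sliders, header = TRUE, sep = ",", comment.char = "#")
    names(df) <- tolower(names(df))
    sliders <- df
  }
  sliders <- as_tibble(sliders)
  if (!all(c("before", "slide", "after") %in% names(sliders))) {
    abort("sliders must have columns before, slide, after")
  }
  sliders[, c("before", "slide", "after")]
}

roles_from_sliders <- function(n, sliders) {
  roles <- rep("fixed", n)
  roles[sliders$slide] <- "sliding"
  roles
}

read_landmarks_tps <- function(path, sliders, flip_y) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lm_at <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (length(lm_at) == 0) abort("no specimen records (no LM= lines found)")
  recs <- list()
  prov <- list()
  bounds <- c(lm_at, length(lines) + 1L)
  for (r in seq_along(lm_at)) {
    block <- lines[lm_at[r]:(bounds[r + 1L] - 1L)]
    start_line <- lm_at[r]
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", block[1], ignore.case = TRUE)))
    if (is.na(k) || k < 1) {
      abort(paste0("malformed LM= line at line ", start_line))
    }
    coord_lines <- block[-1][grepl("^[-+0-9.eE]+[ \t]+[-+0-9.eE]+$", block[-1])]
    if (length(coord_lines) != k) {
      abort(paste0(
        "record starting at line ", start_line, " declares LM=", k,
        " but has ", length(coord_lines), " coordinate lines"
      ))
    }
    xy <- do.call(rbind, lapply(coord_lines, function(l) {
      as.numeric(strsplit(l, "[ \t]+")[[1]])
    }))
    if (any(!is.finite(xy))) {
      abort(paste0("non-numeric coordinate in record starting at line ", start_line))
    }
    id_line <- grep("^ID\\s*=", block, ignore.case = TRUE, value = TRUE)
    id <- if (length(id_line) > 0) {
      sub("^ID\\s*=\\s*", "", id_line[1], ignore.case = TRUE)
    } else {
      paste0("specimen_", r)
    }
    scale_line <- grep("^SCALE\\s*=", block, ignore.case = TRUE, value = TRUE)
    if (length(scale_line) > 0) {
      sc <- as.numeric(sub("^SCALE\\s*=\\s*", "", scale_line[1], ignore.case = TRUE))
      if (!is.finite(sc)) abort(paste0("malformed SCALE= in record for ", id))
      xy <- xy * sc
    }
    if (flip_y) xy[, 2] <- -xy[, 2]
    recs[[r]] <- tibble(
      specimen_id = id,
      landmark = seq_len(k),
      role = roles_from_sliders(k, sliders),
      x = xy[, 1], y = xy[, 2]
    )
    prov[[r]] <- tibble(specimen_id = id, source = path, line = start_line, mirrored = FALSE)
  }
  df <- dplyr::bind_rows(recs)
  if (anyDuplicated(unique(df$specimen_id)) > 0 ||
    length(unique(df$specimen_id)) < length(recs)) {
    dup <- names(which(table(vapply(recs, function(r) r$specimen_id[1], "")) > 1))
    abort(paste0("duplicate specimen_id: ", paste(dup, collapse = ", ")))
  }
  out <- landmark_table(df, sliders)
  attr(out, "provenance") <- dplyr::bind_rows(prov)
  out
}

read_landmarks_csv <- function(path, sliders, flip_y) {
  df <- tryCatch(
    read.table(path, header = TRUE, sep = ",", comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) abort(paste0("cannot parse CSV: ", conditionMessage(e)))
  )
  if (nrow(df) == 0) abort("no specimen records")
  names(df) <- tolower(names(df))
  if (!all(c("specimen_id", "landmark", "x", "y") %in% names(df))) {
    abort("CSV must have columns specimen_id, landmark, x, y (plus optional role, metadata)")
  }
  if (!is.numeric(df$x) || !is.numeric(df$y)) {
    bad <- df$specimen_id[suppressWarnings(is.na(as.numeric(df$x)) | is.na(as.numeric(df$y)))]
    abort(paste0(
      "non-numeric coordinate for specimen(s): ",
      paste(unique(bad), collapse = ", ")
    ))
  }
  k <- max(df$landmark)
  counts <- table(df$specimen_id)
  if (length(unique(counts)) > 1 || any(counts != k)) {
    abort(paste0(
      "wrong landmark count for specimen(s): ",
      paste(names(counts)[counts != k], collapse = ", ")
    ))
  }
  if (!"role" %in% names(df)) {
    df$role <- roles_from_sliders(k, sliders)[df$landmark]
  }
  if (flip_y) df$y <- -df$y
  out <- landmark_table(df, sliders)
  prov <- tibble(
    specimen_id = unique(df$specimen_id), source = path, line = NA_integer_,
    mirrored = FALSE
  )
  right <- lm_meta(out)$specimen_id[lm_meta(out)$side == "right"]
  if (length(right) > 0) {
    out <- mirror_landmarks(out, specimens = right)
    prov$mirrored[prov$specimen_id %in% right] <- TRUE
  }
  attr(out, "provenance") <- prov
  out
}

#' Write landmark configurations to a TPS or CSV file
#'
#' Coordinates are written with full `%.17g` precision so that a
#' write-then-read round trip reproduces the doubles exactly.
#'
#' @param x A `landmark_tbl`.
#' @param path Output file.
#' @param format `"tps"` or `"csv"` (default guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(x, path, format = c("auto", "tps", "csv")) {
  format <- match.arg(format)
  if (nrow(x) == 0) abort("cannot write an empty landmark table")
  if (format == "auto") {
    format <- if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv"
  }
  x <- x[order(match(x$specimen_id, unique(x$specimen_id)), x$landmark), ]
  num <- function(v) sprintf("%.17g", v)
  if (format == "tps") {
    blocks <- lapply(split(x, factor(x$specimen_id, levels = unique(x$specimen_id))), function(sub) {
      c(
        sprintf("LM=%d", nrow(sub)),
        paste(num(sub$x), num(sub$y)),
        sprintf("ID=%s", sub$specimen_id[1])
      )
    })
    writeLines(unlist(blocks), path)
  } else {
    df <- as_tibble(x)
    df$x <- num(df$x)
    df$y <- num(df$y)
    write.table(df, path,
      sep = ",", quote = FALSE, row.names = FALSE,
      col.names = TRUE
    )
  }
  invisible(path)
}

#' Mirror landmark configurations to the opposite side
#'
#' Negates x about the per-specimen centroid (so the centroid is preserved)
#' and toggles the `side` flag. Mirroring is an isometry: all inter-landmark
#' distances and the centroid size are unchanged, and applying it twice
#' restores the original coordinates exactly.
#'
#' @param x A `landmark_tbl`.
#' @param specimens Character vector of specimen ids to mirror (default all).
#' @return The mirrored `landmark_tbl`.
#' @export
mirror_landmarks <- function(x, specimens = NULL) {
  if (is.null(specimens)) specimens <- unique(x$specimen_id)
  sel <- x$specimen_id %in% specimens
  cx <- stats::ave(x$x, x$specimen_id, FUN = mean)
  x$x[sel] <- 2 * cx[sel] - x$x[sel]
  x$side[sel] <- ifelse(x$side[sel] == "left", "right", "left")
  x
}
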