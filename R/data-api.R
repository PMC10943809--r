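#' Deterministic content-derived GUIDs
#'
#' Neuron images get globally unique identifiers that persist across data
#' versions. For synthetic data the GUID is derived from the image's stable
#' content identity (modality, id, sample, index), so regenerating a dataset
#' yields the same GUIDs.
#'
#' @param modality `"EM"` or `"LM"`.
#' @param image_id The stable image identifier (body id for EM neurons,
#'   voxel-set id for LM images).
#' @param variant Image variant (`"original"` or `"combined"`), so a neuron
#'   and its mirror augmentation get distinct GUIDs.
#' @return Character GUID.
#' @export
make_guid <- function(modality, image_id, variant = "original") {
  paste0("nb-", substr(rlang::hash(list(as.character(modality),
                                        as.character(image_id),
                                        as.character(variant))), 1, 16))
}

#' Data config with constant interpolation
#'
#' The config document carries the anatomical areas, base path prefixes and a
#' constants table mapping short keys to long common values. Documents store
#' `"@key"` strings in place of the long values; [expand_constants()]
#' restores them and [compress_constants()] re-abbreviates. Expansion errors
#' on a short key with no entry, so every key used in a published document
#' must resolve.
#'
#' @param anatomical_areas Character vector.
#' @param constants Named character vector/list: short key -> long value.
#' @param prefixes Named list of base path prefixes.
#' @param version Schema/data version string.
#' @return A list of class `data_config`.
#' @export
data_config <- function(anatomical_areas = "Brain",
                        constants = list(),
                        prefixes = list(), version = "v1.0.0") {
  structure(list(anatomicalAreas = as.list(anatomical_areas),
                 constants = as.list(constants),
                 prefixes = as.list(prefixes),
                 version = version),
            class = "data_config")
}

#' @rdname data_config
#' @param doc A (possibly nested) list document.
#' @param config A [data_config()].
#' @export
expand_constants <- function(doc, config) {
  walk_strings(doc, function(s) {
    if (startsWith(s, "@")) {
      key <- substring(s, 2)
      val <- config$constants[[key]]
      if (is.null(val)) abort(sprintf("constant key '@%s' does not resolve", key))
      val
    } else s
  })
}

#' @rdname data_config
#' @export
compress_constants <- function(doc, config) {
  if (length(config$constants) == 0L) return(doc)
  longs <- unlist(config$constants)
  walk_strings(doc, function(s) {
    hit <- match(s, longs)
    if (!is.na(hit)) paste0("@", names(longs)[hit]) else s
  })
}

walk_strings <- function(x, f) {
  if (is.list(x)) return(lapply(x, walk_strings, f = f))
  if (is.character(x) && length(x) == 1L) return(f(x))
  if (is.character(x)) return(vapply(x, f, character(1), USE.NAMES = FALSE))
  x
}

#' Validate a document against a shipped JSON schema
#'
#' Checks a document against one of the versioned schemas shipped with the
#' package (and copied into every bucket under `<VER>/schemas/`):
#' `ImageLookup`, `PrecomputedMatches` or `DataConfig`. The checker covers
#' the subset of JSON Schema the shipped schemas use: `type`, `required`,
#' `properties`, `items` and `enum`, applied recursively.
#'
#' @param doc A list document (e.g. from [jsonlite::read_json()]).
#' @param schema_name Schema name, or a path to a schema JSON file.
#' @return `TRUE` if valid, otherwise a character vector of errors.
#' @export
validate_doc <- function(doc, schema_name) {
  path <- if (file.exists(schema_name)) schema_name
          else system.file("extdata", "schemas", paste0(schema_name, ".json"),
                           package = "colordepth")
  if (!nzchar(path) || !file.exists(path))
    abort(sprintf("unknown schema '%s'", schema_name))
  schema <- jsonlite::read_json(path)
  errs <- check_schema(doc, schema, "$")
  if (length(errs) == 0L) TRUE else errs
}

check_schema <- function(x, schema, at) {
  errs <- character(0)
  ty <- schema$type
  if (!is.null(ty)) {
    ok <- switch(ty,
      object = is.list(x) && (length(x) == 0L || !is.null(names(x))),
      array = is.list(x) && is.null(names(x)) || (is.atomic(x) && length(x) != 1L),
      string = is.character(x) && length(x) == 1L,
      number = is.numeric(x) && length(x) == 1L,
      integer = is.numeric(x) && length(x) == 1L && x == round(x),
      boolean = is.logical(x) && length(x) == 1L,
      TRUE)
    if (!isTRUE(ok))
      return(sprintf("%s: expected %s", at, ty))
  }
  if (!is.null(schema$enum)) {
    if (!x %in% unlist(schema$enum))
      errs <- c(errs, sprintf("%s: value '%s' not in enum", at, x))
  }
  if (identical(ty, "object")) {
    for (req in unlist(schema$required))
      if (is.null(x[[req]]))
        errs <- c(errs, sprintf("%s: missing required property '%s'", at, req))
    for (nm in names(schema$properties)) {
      if (!is.null(x[[nm]]))
        errs <- c(errs, check_schema(x[[nm]], schema$properties[[nm]],
                                     paste0(at, ".", nm)))
    }
  }
  if (identical(ty, "array") && !is.null(schema$items)) {
    items <- if (is.list(x) && is.null(names(x))) x else as.list(x)
    for (i in seq_along(items))
      errs <- c(errs, check_schema(items[[i]], schema$items,
                                   sprintf("%s[%d]", at, i)))
  }
  errs
}

# ---- bucket layout ---------------------------------------------------------

#' Write the versioned match-metadata bucket layout
#'
#' Materializes precomputed match tables as the static JSON tree of the open
#' data API:
#' ```
#' root/current.txt                     # names the current version
#' root/<VER>/config.json               # DataConfig (areas, constants, prefixes)
#' root/<VER>/schemas/*.json            # versioned document schemas
#' root/<VER>/metadata/by_body/<id>.json    # EM neuron image lookup
#' root/<VER>/metadata/by_line/<id>.json    # driver line image lookup
#' root/<VER>/metadata/cdsresults/<image_id>.json  # per-image match lists
#' ```
#' Image metadata is denormalized into every match document so a client needs
#' a single request per lookup; long common values are stored as `"@key"`
#' constants resolved through config.json. Existing version directories are
#' never modified: older versions stay readable, and `current.txt` is the
#' only file rewritten when a new version is published.
#'
#' @param tables A `match_tables` object from [precompute_all()].
#' @param em_lib,lm_lib The [cdm_library()] tibbles behind the tables.
#' @param root Bucket root directory.
#' @param version Version string, e.g. `"v1.0.0"`.
#' @param config A [data_config()]; constants are augmented with the
#'   alignment-space and library names.
#' @param max_lines,max_per_line Line cap applied to EM->LM documents.
#' @return `root`, invisibly.
#' @export
write_bucket_layout <- function(tables, em_lib, lm_lib, root, version = "v1.0.0",
                                config = NULL, max_lines = 300L,
                                max_per_line = Inf) {
  stopifnot(inherits(tables, "match_tables"))
  space <- lib_space(em_lib)
  config <- config %||% data_config(
    constants = list(AS = space$name, EMLIB = "synthetic-em", LMLIB = "synthetic-lm"),
    prefixes = list(imagery_base = "images/"),
    version = version)
  vdir <- file.path(root, version)
  if (dir.exists(vdir))
    abort(sprintf("version directory %s already exists; versions are immutable", vdir))
  for (d in c(file.path(vdir, "schemas"),
              file.path(vdir, "metadata", "by_body"),
              file.path(vdir, "metadata", "by_line"),
              file.path(vdir, "metadata", "cdsresults")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)

  # schemas shipped with the package are copied verbatim into the version
  schema_src <- system.file("extdata", "schemas", package = "colordepth")
  file.copy(list.files(schema_src, full.names = TRUE), file.path(vdir, "schemas"))

  wjson <- function(x, path) jsonlite::write_json(x, path, auto_unbox = TRUE,
                                                  pretty = TRUE, digits = NA, null = "null")
  cfg_doc <- unclass(config)
  wjson(cfg_doc, file.path(vdir, "config.json"))

  img_meta <- function(row, modality) {
    list(id = make_guid(modality, row$image_id, row$variant),
         libraryName = if (modality == "EM") "@EMLIB" else "@LMLIB",
         alignmentSpace = "@AS",
         publishedName = row$neuron_or_line_id,
         sampleId = row$sample_id,
         modality = modality,
         mirrored = !identical(row$variant, "original"),
         files = list(
           CDM = paste0("images/", row$image_id, ".png"),
           CDMInput = paste0("images/", row$image_id, ".png")))
  }
  em_key <- paste0(em_lib$image_id, "|", em_lib$variant)
  lm_key <- paste0(lm_lib$image_id, "|", lm_lib$variant)
  if (anyDuplicated(c(em_key, lm_key)))
    abort("duplicate (image_id, variant) pairs across library entries")
  em_rows <- split(em_lib, seq_len(nrow(em_lib)))
  lm_rows <- split(lm_lib, seq_len(nrow(lm_lib)))
  em_meta <- setNames(lapply(em_rows, img_meta, modality = "EM"), em_key)
  lm_meta <- setNames(lapply(lm_rows, img_meta, modality = "LM"), lm_key)
  guids <- c(vapply(em_meta, `[[`, character(1), "id"),
             vapply(lm_meta, `[[`, character(1), "id"))
  if (anyDuplicated(guids)) abort("GUID collision across library entries")
  guid_of <- setNames(guids, c(em_key, lm_key))

  # image lookups: one doc per EM body, one per LM line
  for (body in unique(em_lib$neuron_or_line_id)) {
    results <- unname(em_meta[em_key[em_lib$neuron_or_line_id == body]])
    wjson(list(results = results),
          file.path(vdir, "metadata", "by_body", paste0(body, ".json")))
  }
  for (line in unique(lm_lib$neuron_or_line_id)) {
    results <- unname(lm_meta[lm_key[lm_lib$neuron_or_line_id == line]])
    wjson(list(results = results),
          file.path(vdir, "metadata", "by_line", paste0(line, ".json")))
  }

  match_doc_row <- function(r, side_meta, mirrored) {
    doc <- list(image = side_meta,
                mirrored = mirrored,
                matchingPixels = r$matched_pixels)
    if (!is.null(r$shape_score)) {
      doc$gradientAreaGap <- r$negative
      doc$shapeScore <- r$shape_score
    }
    doc$normalizedScore <- if (!is.null(r$shape_score)) r$shape_score else r$matched_pixels
    doc
  }

  # EM -> LM documents (grouped + capped per EM target)
  em2lm <- group_and_cap(tables$em_to_lm, max_lines = max_lines,
                         max_per_line = max_per_line)
  for (ei in which(em_lib$variant == "original")) {
    body <- em_lib$neuron_or_line_id[ei]
    rows <- em2lm[em2lm$em_id == body, ]
    results <- lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      match_doc_row(r, lm_meta[[paste0(r$lm_id, "|original")]],
                    mirrored = !identical(r$em_variant, "original"))
    })
    wjson(list(inputImage = em_meta[[em_key[ei]]], results = results),
          file.path(vdir, "metadata", "cdsresults",
                    paste0(guid_of[[em_key[ei]]], ".json")))
  }
  # LM -> EM documents (all EM neurons, ranked)
  for (li in seq_len(nrow(lm_lib))) {
    lm_img <- lm_lib$image_id[li]
    rows <- tables$lm_to_em[tables$lm_to_em$lm_id == lm_img, ]
    rows <- rows[order(rows$rank), ]
    results <- lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      match_doc_row(r, em_meta[[paste0(r$em_image_id, "|", r$em_variant)]],
                    mirrored = !identical(r$em_variant, "original"))
    })
    wjson(list(inputImage = lm_meta[[lm_key[li]]], results = results),
          file.path(vdir, "metadata", "cdsresults",
                    paste0(guid_of[[lm_key[li]]], ".json")))
  }
  writeLines(version, file.path(root, "current.txt"))
  invisible(root)
}

#' Resolve a document from a bucket layout
#'
#' Reads `current.txt` (or uses an explicitly requested older version) and
#' returns the keyed JSON document, with constants expanded through that
#' version's config.
#'
#' @param root Bucket root directory.
#' @param kind One of `"by_body"`, `"by_line"`, `"cdsresults"`.
#' @param id Body id, line id, or image GUID.
#' @param version Optional explicit version (default: current).
#' @param expand Expand `"@key"` constants (default TRUE).
#' @return The document as a list.
#' @export
lookup_doc <- function(root, kind = c("by_body", "by_line", "cdsresults"), id,
                       version = NULL, expand = TRUE) {
  kind <- match.arg(kind)
  curfile <- file.path(root, "current.txt")
  if (!file.exists(curfile)) abort(sprintf("no current.txt under %s", root))
  version <- version %||% readLines(curfile, n = 1L)
  path <- file.path(root, version, "metadata", kind, paste0(id, ".json"))
  if (!file.exists(path))
    abort(sprintf("not found: %s id '%s' in version %s", kind, id, version))
  doc <- jsonlite::read_json(path)
  if (expand) {
    cfg <- jsonlite::read_json(file.path(root, version, "config.json"))
    doc <- expand_constants(doc, data_config(constants = cfg$constants))
  }
  doc
}

#' Validate every document in a bucket version
#'
#' Checks each JSON document under a bucket version against its shipped
#' schema and verifies referential closure: every image id referenced by a
#' cdsresults document must appear in some by_body or by_line lookup.
#'
#' @param root Bucket root.
#' @param version Version to check (default: current).
#' @return `TRUE` invisibly if everything validates; otherwise errors.
#' @export
validate_bucket <- function(root, version = NULL) {
  version <- version %||% readLines(file.path(root, "current.txt"), n = 1L)
  vdir <- file.path(root, version)
  cfg <- jsonlite::read_json(file.path(vdir, "config.json"))
  ok <- validate_doc(cfg, file.path(vdir, "schemas", "DataConfig.json"))
  if (!isTRUE(ok)) abort(paste("config.json invalid:", paste(ok, collapse = "; ")))
  known_ids <- character(0)
  for (kind in c("by_body", "by_line")) {
    for (f in list.files(file.path(vdir, "metadata", kind), full.names = TRUE)) {
      doc <- jsonlite::read_json(f)
      ok <- validate_doc(doc, file.path(vdir, "schemas", "ImageLookup.json"))
      if (!isTRUE(ok)) abort(sprintf("%s invalid: %s", f, paste(ok, collapse = "; ")))
      known_ids <- c(known_ids, vapply(doc$results, `[[`, character(1), "id"))
    }
  }
  for (f in list.files(file.path(vdir, "metadata", "cdsresults"), full.names = TRUE)) {
    doc <- jsonlite::read_json(f)
    ok <- validate_doc(doc, file.path(vdir, "schemas", "PrecomputedMatches.json"))
    if (!isTRUE(ok)) abort(sprintf("%s invalid: %s", f, paste(ok, collapse = "; ")))
    ids <- c(doc$inputImage$id, vapply(doc$results, function(r) r$image$id, character(1)))
    dangling <- setdiff(ids, known_ids)
    if (length(dangling) > 0L)
      abort(sprintf("%s references unknown image id(s): %s", f,
                    paste(dangling, collapse = ", ")))
  }
  invisible(TRUE)
}
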