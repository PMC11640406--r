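#' Write a beat set to disk
#'
#' Two on-disk layouts are supported, both described by a JSON manifest
#' written alongside the data:
#'
#' * `delimited`: a long-format tab-separated signal file with columns
#'   `beat_id`, `lead_index` (1..12), `sample_index` (1..L), `value`
#'   (mV), plus a separate labels file (`beat_id`, `label`).
#' * `rds`: a compact single-file container (an RDS-serialised list with
#'   the signal array, labels and lead names), for fast local round trips.
#'
#' All indexes on disk are 1-based.
#'
#' @param beats A beat-set tibble.
#' @param dir Output directory (created if needed).
#' @param format `"delimited"` or `"rds"`.
#' @param lead_order Declared lead order (12 names, default [lead_names()]).
#' @return Path to the manifest JSON, invisibly.
#' @export
write_beatset <- function(beats, dir, format = c("delimited", "rds"),
                          lead_order = lead_names()) {
  format <- match.arg(format)
  validate_beatset(beats)
  if (length(lead_order) != N_LEADS) {
    abort("`lead_order` must declare exactly 12 leads.",
          class = "cardioish_format_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  L <- ncol(beats$signal[[1]])
  manifest <- list(format = format, lead_order = lead_order,
                   expected_length = L, labels = "labels.tsv")
  if (format == "delimited") {
    long <- beatset_long(beats)
    write.table(
      data.frame(beat_id = long$beat_id, lead_index = long$lead,
                 sample_index = long$sample, value = long$value),
      file.path(dir, "signals.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$signals <- "signals.tsv"
  } else {
    saveRDS(list(signals = beats$signal, beat_id = beats$beat_id,
                 lead_order = lead_order),
            file.path(dir, "signals.rds"))
    manifest$signals <- "signals.rds"
  }
  write.table(data.frame(beat_id = beats$beat_id, label = beats$label),
              file.path(dir, "labels.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a beat set described by a manifest
#'
#' Reads the signal and label files referenced by a dataset manifest
#' (see [write_beatset()]), validates the declared 12-lead order, the
#' consistency of beat lengths and the signal/label correspondence, and
#' maps labels to contiguous integers `1..K` (the original label values
#' are preserved in the `label_names` attribute).
#'
#' @param manifest Path to a manifest JSON, or an equivalent named list
#'   with fields `format`, `signals`, `labels`, `lead_order`,
#'   `expected_length`. Relative data paths resolve against the manifest's
#'   directory.
#' @return A beat-set tibble with attribute `label_names`.
#' @export
read_beatset <- function(manifest) {
  base <- "."
  if (is.character(manifest)) {
    base <- dirname(manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  if (!manifest$format %in% c("delimited", "rds")) {
    abort(sprintf("Unsupported beat-set format '%s'.", manifest$format),
          class = "cardioish_config_error")
  }
  lead_order <- unlist(manifest$lead_order)
  if (length(lead_order) != N_LEADS) {
    abort(sprintf("Manifest declares %d leads; 12 are required.",
                  length(lead_order)),
          class = "cardioish_format_error")
  }
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)

  labels_df <- read.delim(resolve(manifest$labels))
  if (!all(c("beat_id", "label") %in% names(labels_df))) {
    abort("Labels file needs columns `beat_id` and `label`.",
          class = "cardioish_format_error")
  }

  if (manifest$format == "delimited") {
    long <- read.delim(resolve(manifest$signals))
    need <- c("beat_id", "lead_index", "sample_index", "value")
    if (!all(need %in% names(long))) {
      abort("Signals file needs beat_id, lead_index, sample_index, value.",
            class = "cardioish_format_error")
    }
    split_ids <- unique(long$beat_id)
    signals <- lapply(split_ids, function(id) {
      part <- long[long$beat_id == id, ]
      leads <- sort(unique(part$lead_index))
      if (!identical(as.integer(leads), seq_len(N_LEADS))) {
        abort(sprintf("Beat %s is missing lead rows.", id),
              class = "cardioish_format_error")
      }
      L <- max(part$sample_index)
      m <- matrix(NA_real_, N_LEADS, L)
      m[cbind(part$lead_index, part$sample_index)] <- part$value
      if (anyNA(m)) {
        abort(sprintf("Beat %s has missing samples.", id),
              class = "cardioish_format_error")
      }
      rownames(m) <- lead_order
      m
    })
    beat_id <- as.integer(split_ids)
  } else {
    blob <- readRDS(resolve(manifest$signals))
    signals <- blob$signals
    beat_id <- as.integer(blob$beat_id)
  }

  Ls <- vapply(signals, ncol, integer(1))
  if (length(unique(Ls)) != 1L) {
    abort(sprintf("Beat %s has length %d; expected a single common length.",
                  beat_id[which(Ls != Ls[1])[1]], Ls[which(Ls != Ls[1])[1]]),
          class = "cardioish_format_error")
  }
  if (!is.null(manifest$expected_length) && Ls[1] != manifest$expected_length) {
    abort(sprintf("Beats have length %d but the manifest declares %d.",
                  Ls[1], manifest$expected_length),
          class = "cardioish_format_error")
  }
  missing_lab <- setdiff(beat_id, labels_df$beat_id)
  if (length(missing_lab) > 0L) {
    abort(sprintf("Beat %s has no label.", missing_lab[1]),
          class = "cardioish_format_error")
  }
  orphan <- setdiff(labels_df$beat_id, beat_id)
  if (length(orphan) > 0L) {
    abort(sprintf("Labels file references beat %s absent from the signals.",
                  orphan[1]),
          class = "cardioish_format_error")
  }
  raw_labels <- labels_df$label[match(beat_id, labels_df$beat_id)]
  levels <- sort(unique(raw_labels))
  out <- new_beatset(tibble::tibble(
    beat_id = beat_id,
    label = match(raw_labels, levels),
    signal = signals
  ))
  attr(out, "label_names") <- levels
  validate_beatset(out)
  out
}

#' Write / read a feature table as CSV
#'
#' The on-disk layout is one row per beat: `beat_id`, `label`, then the
#' 144 feature columns `f001..f144`.
#'
#' @param features Feature tibble from [extract_features()].
#' @param path CSV path.
#' @return `write_features` returns `path` invisibly; `read_features`
#'   returns the feature tibble.
#' @export
write_features <- function(features, path) {
  stopifnot(all(feature_names() %in% names(features)))
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- tibble::as_tibble(read.csv(path))
  missing <- setdiff(feature_names(), names(out))
  if (length(missing) > 0L) {
    abort(sprintf("Feature CSV is missing column %s.", missing[1]),
          class = "cardioish_format_error")
  }
  out
}

#' Write / read an INCA selection report as JSON
#'
#' The report records the NCA weights, the full ranking, the prefix loss
#' curve, the chosen prefix size and the selected 1-based feature indexes.
#'
#' @param selection A `cardioish_selection` from [inca()].
#' @param path JSON path.
#' @return `write_selection` returns `path` invisibly; `read_selection`
#'   the parsed report list.
#' @export
write_selection <- function(selection, path) {
  stopifnot(inherits(selection, "cardioish_selection"))
  jsonlite::write_json(
    list(weights = selection$weights,
         ranking = selection$idx,
         loss_curve = list(size = selection$loss_curve$size,
                           loss = selection$loss_curve$loss),
         chosen_size = selection$size,
         chosen_indexes_1based = selection$sel_indexes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a Cardioish sentence with its JSON sidecar
#'
#' The sentence itself is written as one line of concatenated 3-character
#' symbols; a sidecar JSON (same path with `.json` appended) records the
#' token list, per-symbol frequencies and the Shannon entropy.
#'
#' @param sentence A `cardioish_sentence`.
#' @param path Text-file path.
#' @param sidecar Sidecar JSON path (default `paste0(path, ".json")`).
#' @return `path`, invisibly.
#' @export
write_sentence <- function(sentence, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(sentence, "cardioish_sentence"))
  writeLines(format(sentence), path)
  dist <- if (length(sentence$tokens) > 0L) {
    symbol_distribution(sentence$tokens)
  } else {
    tibble::tibble(symbol = cardioish_alphabet(), count = 0L, probability = NA_real_)
  }
  jsonlite::write_json(
    list(tokens = sentence$tokens,
         nosf = sentence$nosf,
         frequencies = setNames(as.list(dist$count), dist$symbol),
         entropy_bits = if (length(sentence$tokens)) attr(dist, "entropy_bits") else NA),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Cardioish sentence text file
#'
#' @param path Text file holding one concatenated sentence.
#' @return A `cardioish_sentence`.
#' @export
read_sentence <- function(path) {
  tokens <- tokenize_sentence(paste(readLines(path, warn = FALSE), collapse = ""))
  new_sentence(tokens, match(tokens, cardioish_alphabet()))
}

#' Export a connectome graph
#'
#' Writes the directed weighted graph in GraphML, DOT or node-link JSON.
#' Node identifiers are the Cardioish symbols; edge weights are stored in
#' an integer `count` attribute. All 12 nodes are always present, even
#' when isolated.
#'
#' @param graph A `cardioish_connectome`.
#' @param path Output file path.
#' @param format `"graphml"`, `"dot"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(graph, path, format = c("graphml", "dot", "json")) {
  stopifnot(inherits(graph, "cardioish_connectome"))
  format <- match.arg(format)
  switch(format,
    graphml = igraph::write_graph(as_igraph(graph), path, format = "graphml"),
    dot = {
      lines <- c("digraph cardioish {",
                 sprintf("  \"%s\";", graph$nodes),
                 sprintf("  \"%s\" -> \"%s\" [count=%d];",
                         graph$edges$from, graph$edges$to, graph$edges$count),
                 "}")
      writeLines(lines, path)
    },
    json = jsonlite::write_json(
      list(directed = TRUE, mode = graph$mode,
           nodes = lapply(graph$nodes, function(s) list(id = s)),
           links = purrr::pmap(graph$edges, function(from, to, count) {
             list(source = from, target = to, count = count)
           })),
      path, auto_unbox = TRUE, digits = NA)
  )
  invisible(path)
}

#' Read a connectome graph file
#'
#' Inverse of [write_connectome()] for all three formats (the DOT reader
#' understands the package's own DOT output).
#'
#' @param path Graph file path.
#' @param format `"graphml"`, `"dot"` or `"json"`.
#' @return A `cardioish_connectome` (mode `"sentence-transitions"` is not
#'   recoverable from GraphML/DOT and defaults to the file's declared mode
#'   for JSON, otherwise `"sentence-transitions"`).
#' @export
read_connectome <- function(path, format = c("graphml", "dot", "json")) {
  format <- match.arg(format)
  alpha <- cardioish_alphabet()
  out <- switch(format,
    graphml = {
      g <- igraph::read_graph(path, format = "graphml")
      e <- igraph::as_data_frame(g, what = "edges")
      list(edges = tibble::tibble(from = e$from, to = e$to,
                                  count = as.integer(e$count)),
           mode = "sentence-transitions")
    },
    dot = {
      lines <- readLines(path, warn = FALSE)
      m <- regmatches(lines,
        regexec('"([A-Za-z0-9]{3})" -> "([A-Za-z0-9]{3})" \\[count=([0-9]+)\\]', lines))
      hits <- Filter(function(x) length(x) == 4L, m)
      list(edges = tibble::tibble(
        from = vapply(hits, `[`, "", 2L),
        to = vapply(hits, `[`, "", 3L),
        count = as.integer(vapply(hits, `[`, "", 4L))),
        mode = "sentence-transitions")
    },
    json = {
      j <- jsonlite::read_json(path, simplifyVector = FALSE)
      links <- j$links
      list(edges = tibble::tibble(
        from = vapply(links, function(l) l$source, ""),
        to = vapply(links, function(l) l$target, ""),
        count = vapply(links, function(l) as.integer(l$count), 1L)),
        mode = j$mode %||% "sentence-transitions")
    }
  )
  edges <- out$edges |>
    dplyr::arrange(match(.data$from, alpha), match(.data$to, alpha))
  bad <- setdiff(unique(c(edges$from, edges$to)), alpha)
  if (length(bad) > 0L) {
    abort(sprintf("Graph file contains unknown symbol '%s'.", bad[1]),
          class = "cardioish_parse_error")
  }
  structure(list(nodes = alpha, edges = edges, mode = out$mode),
            class = "cardioish_connectome")
}
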