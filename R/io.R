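#' Read an anatomical network from an adjacency CSV
#'
#' The expected dialect is a square 0/1 table with a header row and the node
#' labels in the first column, in the same order as the columns (UTF-8).
#' Nothing is symmetrised silently: an asymmetric matrix is an error.
#'
#' Node classes come from, in order of preference: the `metadata` sidecar
#' file, the bundled limb label-to-class table (see
#' [limb_node_classes()]), or the `node_class` argument. The sidecar is a CSV
#' with columns `label`, `node_class` and optionally `region`, preceded by
#' optional comment lines of the form `# key: value` carrying network-level
#' metadata (`limb`, `side`, `condition`, `system`).
#'
#' @param path path to the adjacency CSV.
#' @param metadata optional path to the sidecar metadata file.
#' @param node_class optional per-node class vector, used when no sidecar is
#'   given and a label is absent from the bundled table.
#' @return an [anatomical_network()].
#' @export
read_adjacency_csv <- function(path, metadata = NULL, node_class = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, row.names = NULL,
                         stringsAsFactors = FALSE)
  labels <- trimws(as.character(raw[[1]]))
  A <- as.matrix(raw[, -1, drop = FALSE])
  col_labels <- trimws(colnames(A))
  if (length(col_labels) == length(labels) && !identical(col_labels, labels)) {
    stop_limbnet("row and column labels differ (same order required)",
                 "limbnet_error_label_mismatch")
  }

  meta <- list()
  region <- NULL
  if (!is.null(metadata)) {
    side <- read_sidecar(metadata)
    meta <- side$meta
    node_class <- side$node_class
    region <- side$region
  } else if (is.null(node_class)) {
    lookup <- limb_node_classes()
    known <- labels %in% names(lookup$node_class)
    if (all(known)) {
      node_class <- lookup$node_class[labels]
      region <- lookup$region[labels]
    }
  }
  anatomical_network(A, labels = labels, node_class = node_class,
                     region = region, meta = meta)
}

read_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  is_meta <- grepl("^\\s*#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- sub("^\\s*#\\s*", "", ln)
    if (grepl(":", kv, fixed = TRUE)) {
      key <- trimws(sub(":.*$", "", kv))
      val <- trimws(sub("^[^:]*:", "", kv))
      meta[[key]] <- val
    }
  }
  tab <- utils::read.csv(text = paste(lines[!is_meta], collapse = "\n"),
                         stringsAsFactors = FALSE)
  lbl <- trimws(as.character(tab$label))
  list(meta = meta,
       node_class = stats::setNames(as.character(tab$node_class), lbl),
       region = if ("region" %in% names(tab)) {
         stats::setNames(as.character(tab$region), lbl)
       })
}

#' Write an anatomical network to an adjacency CSV (plus sidecar)
#'
#' Round-trips exactly: `read_adjacency_csv(write_adjacency_csv(net))`
#' reproduces labels, adjacency and node classes. Repeated writes of the same
#' network are byte-identical.
#'
#' @param net an [anatomical_network()].
#' @param path output CSV path.
#' @param metadata optional sidecar path; defaults to `path` with a
#'   `.meta.csv` extension. Use `NA` to skip the sidecar.
#' @return `path`, invisibly.
#' @export
write_adjacency_csv <- function(net, path, metadata = NULL) {
  if (is.null(metadata)) metadata <- sub("\\.csv$", "", path)
  A <- net$adjacency
  header <- paste(c("", quote_csv(colnames(A))), collapse = ",")
  rows <- vapply(seq_len(nrow(A)), function(i) {
    paste(c(quote_csv(rownames(A)[i]), format(A[i, ], trim = TRUE)),
          collapse = ",")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con)

  if (!is.na(metadata)) {
    metadata <- paste0(metadata, ".meta.csv")
    mcon <- file(metadata, open = "wb")
    on.exit(close(mcon), add = TRUE)
    mlines <- character(0)
    for (key in names(net$meta)) {
      mlines <- c(mlines, sprintf("# %s: %s", key, net$meta[[key]]))
    }
    mlines <- c(mlines, "label,node_class,region",
                paste(quote_csv(net$labels), net$node_class,
                      ifelse(is.na(net$region), "", net$region), sep = ","))
    writeLines(mlines, mcon)
  }
  invisible(path)
}

quote_csv <- function(x) {
  need <- grepl("[,\"\n]", x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

#' Export an anatomical network to GraphML
#'
#' Node class and region travel as node attributes.
#'
#' @param net an [anatomical_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::V(g)$region <- ifelse(is.na(igraph::V(g)$region), "",
                                igraph::V(g)$region)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Bundled label-to-class table for human limb networks
#'
#' The table lists the bones/cartilages and muscles of the human upper and
#' lower limb by the names used in anatomical descriptions, with the class
#' (`bone_cartilage`/`muscle`), the limb (`UL`/`LL`) and a default region
#' assignment (girdle and stylopod structures, and the muscles attached to
#' them, are proximal; zeugopod and autopod structures are distal). It is the
#' fallback used by [read_adjacency_csv()] when no sidecar is given, and it is
#' editable: pass your own table of the same shape to downstream functions.
#'
#' @return a list with named character vectors `node_class` and `region`.
#' @export
limb_node_classes <- function() {
  path <- system.file("extdata", "limb_node_classes.csv", package = "limbnet")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lbl <- trimws(tab$label)
  list(node_class = stats::setNames(tab$node_class, lbl),
       region = stats::setNames(tab$region, lbl))
}

#' Serial-correspondence map between upper- and lower-limb labels
#'
#' Comparing upper-limb with lower-limb partitions requires an explicit
#' correspondence between labels (humerus-femur, metacarpal-metatarsal, and
#' so on), because shared structure cannot be inferred from string equality.
#' The bundled table covers the widely accepted bone correspondences and is a
#' synthetic, editable stand-in: review it before drawing anatomical
#' conclusions, and extend it with muscle correspondences as needed.
#'
#' @param path optional path to an alternative two-column CSV
#'   (upper-limb label, lower-limb label).
#' @return a named character vector mapping UL labels to LL labels.
#' @export
serial_homology_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "serial_homology_map.csv",
                        package = "limbnet")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(trimws(tab[[2]]), trimws(tab[[1]]))
}

#' Read a grouping hypothesis (functional or developmental groups)
#'
#' @param path two-column CSV: label, group.
#' @param kind `"functional"` or `"developmental"`.
#' @return a named character vector (label -> group) with attribute `kind`.
#' @export
read_grouping_csv <- function(path, kind = c("functional", "developmental")) {
  kind <- match.arg(kind)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  grp <- stats::setNames(trimws(as.character(tab[[2]])),
                         trimws(as.character(tab[[1]])))
  if (any(grp == "" | is.na(grp))) {
    stop_limbnet("group labels must be non-empty",
                 "limbnet_error_grouping")
  }
  attr(grp, "kind") <- kind
  grp
}

#' Read a region map from a two-column CSV
#'
#' @param path two-column CSV: label, region ("proximal"/"distal").
#' @return a [region_map()].
#' @export
read_region_map_csv <- function(path) {
  region_map(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Import the deposited limb adjacency matrices
#'
#' Importer for a local copy of the published limb adjacency-matrix deposit
#' (one CSV per limb/system, in the dialect accepted by
#' [read_adjacency_csv()], classes resolved through [limb_node_classes()]).
#' The deposit must be downloaded once by the user; this function performs no
#' network access.
#'
#' @param dir directory containing the deposited CSV files.
#' @return a named list of [anatomical_network()] objects, one per file.
#' @export
read_limb_deposit <- function(dir) {
  if (!dir.exists(dir)) {
    stop_limbnet(sprintf("deposit directory not found: %s", dir),
                 "limbnet_error_missing_deposit")
  }
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[!grepl("\\.meta\\.csv$", files)]
  if (!length(files)) {
    stop_limbnet("no adjacency CSV files found in deposit directory",
                 "limbnet_error_missing_deposit")
  }
  nets <- lapply(files, read_adjacency_csv)
  names(nets) <- sub("\\.csv$", "", basename(files))
  nets
}
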