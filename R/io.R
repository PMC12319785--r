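# File formats. The dense connectivity container is a plain-text bundle
# (a directory of TSV matrices plus JSON metadata); behavior is CSV,
# the parcellation JSON, structural connectomes and ground truth TSV.
# Numeric values are written with 17 significant digits so write/read
# round-trips are exact on doubles.

.fmt_num <- function(x) sprintf("%.17g", x)

.write_num_tsv <- function(m, path, col_names = NULL) {
  m <- as.matrix(m)
  txt <- apply(m, 1, function(r) paste(.fmt_num(r), collapse = "\t"))
  if (!is.null(col_names)) txt <- c(paste(col_names, collapse = "\t"), txt)
  writeLines(txt, path)
}

.read_num_tsv <- function(path, header = FALSE) {
  as.matrix(utils::read.delim(path, header = header))
}

#' Write a connectivity container
#'
#' Serializes a `conn_tensor` plus its grid geometry to a directory:
#' `meta.json` (dimensions, band/window edges, seed), `geometry.tsv`,
#' `pairs.tsv`, and one `values/<band>__<window>__<task>__s<session>.tsv`
#' matrix (connections x subjects) per slice.
#'
#' @param tensor A `conn_tensor`.
#' @param geometry Geometry data.frame.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_conn_tensor <- function(tensor, geometry, dir) {
  stopifnot(inherits(tensor, "conn_tensor"))
  dir.create(file.path(dir, "values"), recursive = TRUE,
             showWarnings = FALSE)
  meta <- list(n_connections = nrow(tensor$pairs),
               n_subjects = tensor$n_subjects,
               n_sessions = 2L,
               tasks = c("naming", "visual"),
               bands_hz = tensor$bands,
               windows_ms = tensor$windows,
               seed = tensor$seed)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(dir, "meta.json"))
  geo <- geometry
  for (cl in c("x", "y", "z")) geo[[cl]] <- .fmt_num(geo[[cl]])
  utils::write.table(geo, file.path(dir, "geometry.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tensor$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (b in names(tensor$bands)) for (w in names(tensor$windows))
    for (task in c("naming", "visual")) for (d in 1:2)
      .write_num_tsv(tensor$values[, , d, task, b, w],
                     file.path(dir, "values",
                               sprintf("%s__%s__%s__s%d.tsv", b, w, task, d)))
  invisible(dir)
}

#' Read a connectivity container
#'
#' Inverse of [write_conn_tensor()]; validates the bundle layout and
#' reports the missing file or field on schema violations.
#'
#' @param dir Container directory.
#' @return List with `tensor` (a `conn_tensor`) and `geometry`.
#' @export
read_conn_tensor <- function(dir) {
  metaf <- file.path(dir, "meta.json")
  if (!file.exists(metaf))
    stop("not a connectivity container: missing meta.json", call. = FALSE)
  meta <- jsonlite::fromJSON(readLines(metaf), simplifyVector = TRUE)
  for (f in c("n_connections", "n_subjects", "bands_hz", "windows_ms"))
    if (is.null(meta[[f]]))
      stop("meta.json missing field: ", f, call. = FALSE)
  geometry <- utils::read.delim(file.path(dir, "geometry.tsv"),
                                stringsAsFactors = FALSE)
  need <- c("point_id", "x", "y", "z", "hemisphere", "parcel_id")
  miss <- setdiff(need, names(geometry))
  if (length(miss))
    stop("geometry.tsv missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  pairs <- as.matrix(utils::read.delim(file.path(dir, "pairs.tsv")))
  bands <- lapply(meta$bands_hz, as.numeric)
  windows <- lapply(meta$windows_ms, as.numeric)
  bn <- names(bands); wn <- names(windows)
  m <- meta$n_connections; ns <- meta$n_subjects
  values <- array(NA_real_, dim = c(m, ns, 2L, 2L, length(bn), length(wn)),
                  dimnames = list(NULL, NULL, session = c("1", "2"),
                                  task = c("naming", "visual"),
                                  band = bn, window = wn))
  for (b in bn) for (w in wn) for (task in c("naming", "visual"))
    for (d in 1:2) {
      f <- file.path(dir, "values",
                     sprintf("%s__%s__%s__s%d.tsv", b, w, task, d))
      if (!file.exists(f))
        stop("missing values slice: ", basename(f), call. = FALSE)
      values[, , d, task, b, w] <- .read_num_tsv(f)
    }
  tensor <- structure(list(values = values, pairs = pairs, bands = bands,
                           windows = windows, n_subjects = ns,
                           seed = meta$seed),
                      class = "conn_tensor")
  list(tensor = tensor, geometry = geometry)
}

#' Write / read the behavior table
#'
#' CSV with columns `subject`, `fluency_s`, `fluency_animal`,
#' `ran_ras_mean`. The reader errors naming any missing column.
#'
#' @param behavior Behavior data.frame.
#' @param path CSV path.
#' @return `write_behavior`: `path` invisibly; `read_behavior`: the
#'   validated data.frame.
#' @export
write_behavior <- function(behavior, path) {
  utils::write.csv(behavior, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  b <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "fluency_s", "fluency_animal", "ran_ras_mean")
  miss <- setdiff(need, names(b))
  if (length(miss))
    stop("behavior file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(b$subject))
    stop("duplicate subject rows in behavior file", call. = FALSE)
  if (!all(vapply(b[need[-1]], function(x) all(is.finite(x)), TRUE)))
    stop("non-finite behavioral scores", call. = FALSE)
  b
}

#' Write / read a parcellation
#'
#' JSON array of parcel records (`parcel_id`, `name`, `hemisphere`,
#' `included`, centroid coordinates).
#'
#' @param parcellation Parcellation data.frame.
#' @param path JSON path.
#' @return `write_parcellation`: `path` invisibly;
#'   `read_parcellation`: the validated data.frame.
#' @export
write_parcellation <- function(parcellation, path) {
  writeLines(jsonlite::toJSON(parcellation, dataframe = "rows",
                              digits = NA, pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  p <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  need <- c("parcel_id", "name", "hemisphere", "included")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("parcellation missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(p$parcel_id))
    stop("duplicate parcel ids", call. = FALSE)
  p
}

#' Write / read structural connectomes
#'
#' Single TSV edge list with columns `subject`, `parcel_a`, `parcel_b`,
#' `weight`, containing every unordered parcel pair once (zeros
#' included, so the node set is recoverable). The reader rejects
#' conflicting duplicate entries (`(a,b)` and `(b,a)` with different
#' weights).
#'
#' @param connectomes List of symmetric weight matrices with parcel-id
#'   dimnames.
#' @param path TSV path.
#' @return `write_structural`: `path` invisibly; `read_structural`: a
#'   list of symmetric weight matrices.
#' @export
write_structural <- function(connectomes, path) {
  rows <- lapply(seq_along(connectomes), function(s) {
    W <- connectomes[[s]]
    ut <- which(upper.tri(W), arr.ind = TRUE)
    data.frame(subject = s,
               parcel_a = rownames(W)[ut[, 1]],
               parcel_b = colnames(W)[ut[, 2]],
               weight = .fmt_num(W[ut]))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_structural
#' @export
read_structural <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(subject = "integer",
                                        parcel_a = "character",
                                        parcel_b = "character",
                                        weight = "numeric"))
  need <- c("subject", "parcel_a", "parcel_b", "weight")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("structural file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(d$weight < 0)) stop("negative streamline weight", call. = FALSE)
  if (any(d$parcel_a == d$parcel_b))
    stop("self-pair in structural edge list", call. = FALSE)
  key <- paste(d$subject, pmin(d$parcel_a, d$parcel_b),
               pmax(d$parcel_a, d$parcel_b))
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    w_by_key <- split(d$weight, key)
    bad <- names(w_by_key)[vapply(w_by_key,
                                  function(w) length(unique(w)) > 1, TRUE)]
    if (length(bad))
      stop("conflicting duplicate structural entries: ",
           paste(utils::head(bad, 5), collapse = "; "), call. = FALSE)
    d <- d[!duplicated(key), , drop = FALSE]
  }
  nodes <- unique(c(d$parcel_a, d$parcel_b))
  nodes <- if (!anyNA(suppressWarnings(as.numeric(nodes))))
    nodes[order(as.numeric(nodes))] else sort(nodes)
  lapply(split(d, d$subject), function(ds) {
    W <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    W[cbind(match(ds$parcel_a, nodes), match(ds$parcel_b, nodes))] <- ds$weight
    W[cbind(match(ds$parcel_b, nodes), match(ds$parcel_a, nodes))] <- ds$weight
    W
  })
}

#' Write / read the planted ground truth
#'
#' TSV of planted parcel edges with generative parameters and
#' theoretical ICC.
#'
#' @param ground_truth Ground-truth data.frame from
#'   [gen_connectivity()].
#' @param path TSV path.
#' @return `write_ground_truth`: `path` invisibly;
#'   `read_ground_truth`: the data.frame.
#' @export
write_ground_truth <- function(ground_truth, path) {
  gt <- ground_truth
  for (cl in c("mu", "sigma_b", "sigma_e", "theoretical_icc"))
    gt[[cl]] <- .fmt_num(gt[[cl]])
  utils::write.table(gt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
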