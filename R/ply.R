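# PLY 1.0 I/O. Scanner exports (Artec Studio) and the synthetic generator use
# the ascii and binary_little_endian dialects; big-endian files are rejected
# explicitly. Only the vertex element is used -- faces and other elements are
# skipped.

.ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                    short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                    int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_parse_header <- function(lines) {
  if (length(lines) < 2 || trimws(lines[1]) != "ply")
    stop("malformed PLY header: missing 'ply' magic (line 1)")
  fmt_line <- grep("^format ", lines, value = TRUE)
  if (length(fmt_line) != 1)
    stop("malformed PLY header: expected exactly one 'format' line")
  fmt <- strsplit(trimws(fmt_line), "[ \t]+")[[1]]
  if (length(fmt) < 2) stop("malformed PLY header: bad format line")
  format <- fmt[2]
  if (format == "binary_big_endian")
    stop("unsupported PLY dialect: binary_big_endian (use ascii or binary_little_endian)")
  if (!format %in% c("ascii", "binary_little_endian"))
    stop(sprintf("unsupported PLY format '%s'", format))
  elements <- list()
  cur <- NULL
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "element") {
      if (length(tok) != 3 || is.na(suppressWarnings(as.integer(tok[3]))))
        stop(sprintf("malformed PLY header: bad element declaration (line %d)", i))
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur))
        stop(sprintf("malformed PLY header: property before element (line %d)", i))
      if (tok[2] == "list") {
        if (length(tok) != 5)
          stop(sprintf("malformed PLY header: bad list property (line %d)", i))
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[5], type = NA, list = TRUE,
               count_type = tok[3], item_type = tok[4])
      } else {
        if (length(tok) != 3 || !tok[2] %in% names(.ply_type_size))
          stop(sprintf("malformed PLY header: bad property (line %d)", i))
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[3], type = tok[2], list = FALSE)
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  list(format = format, elements = elements)
}

.ply_read_column <- function(raw, start, stride, offset, type, n) {
  size <- .ply_type_size[[type]]
  idx <- as.vector(outer(seq_len(size), (seq_len(n) - 1L) * stride, "+")) +
    start + offset
  bytes <- raw[idx]
  switch(type,
    float = , float32 = readBin(bytes, "double", n, size = 4, endian = "little"),
    double = , float64 = readBin(bytes, "double", n, size = 8, endian = "little"),
    uchar = , uint8 = readBin(bytes, "integer", n, size = 1, signed = FALSE,
                              endian = "little"),
    char = , int8 = readBin(bytes, "integer", n, size = 1, signed = TRUE,
                            endian = "little"),
    ushort = , uint16 = readBin(bytes, "integer", n, size = 2, signed = FALSE,
                                endian = "little"),
    short = , int16 = readBin(bytes, "integer", n, size = 2, signed = TRUE,
                              endian = "little"),
    readBin(bytes, "integer", n, size = 4, endian = "little"))
}

#' Read a PLY point cloud
#'
#' Reads the vertex element of a PLY 1.0 file (ascii or
#' binary_little_endian). Coordinates are taken from the `x`, `y`, `z`
#' properties; normals from `nx`, `ny`, `nz` and colors from `red`, `green`,
#' `blue` when present. Face elements are ignored: the berry detector works
#' on the raw point set.
#'
#' @param path path to a `.ply` file.
#' @return A [point_cloud()].
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  size <- file.size(path)
  raw <- readBin(path, "raw", size)
  m <- grepRaw("end_header", raw[seq_len(min(size, 65536L))], fixed = TRUE)
  if (!length(m)) stop("malformed PLY: no end_header within the first 64 kB")
  payload_start <- m[1] + 9L  # last byte of "end_header"
  if (payload_start < size && raw[payload_start + 1L] == as.raw(13L))
    payload_start <- payload_start + 1L  # \r
  if (payload_start < size && raw[payload_start + 1L] == as.raw(10L))
    payload_start <- payload_start + 1L  # \n
  header_lines <- strsplit(rawToChar(raw[seq_len(m[1] - 1L)]), "\r?\n")[[1]]
  hdr <- .ply_parse_header(header_lines)
  if (!"vertex" %in% names(hdr$elements))
    stop("malformed PLY: no vertex element declared")
  velem <- hdr$elements$vertex
  pnames <- vapply(velem$props, `[[`, "", "name")
  if (!all(c("x", "y", "z") %in% pnames))
    stop("malformed PLY: vertex element must declare x, y, z properties")
  n <- velem$count

  cols <- if (hdr$format == "ascii")
    .ply_read_ascii(raw, payload_start, hdr, velem, pnames, size)
  else
    .ply_read_binary(raw, payload_start, hdr, velem, pnames, size)

  pts <- cbind(cols[["x"]], cols[["y"]], cols[["z"]])
  normals <- NULL
  if (all(c("nx", "ny", "nz") %in% pnames) && n > 0) {
    normals <- cbind(cols[["nx"]], cols[["ny"]], cols[["nz"]])
    len <- sqrt(rowSums(normals^2))
    if (any(len < 1e-6)) {
      warning("zero-length normals in PLY; normals dropped")
      normals <- NULL
    } else normals <- normals / len
  }
  colors <- NULL
  if (all(c("red", "green", "blue") %in% pnames) && n > 0)
    colors <- cbind(cols[["red"]], cols[["green"]], cols[["blue"]])
  point_cloud(pts, normals = normals, colors = colors)
}

.ply_read_ascii <- function(raw, payload_start, hdr, velem, pnames, size) {
  text <- if (payload_start < size)
    rawToChar(raw[(payload_start + 1L):size]) else ""
  lines <- strsplit(text, "\r?\n")[[1]]
  lines <- lines[nzchar(trimws(lines))]
  pos <- 0L
  cols <- NULL
  for (elem in hdr$elements) {
    if (elem$name == "vertex") {
      n <- elem$count
      if (length(lines) - pos < n)
        stop(sprintf("truncated PLY: expected %d vertex lines, found %d",
                     n, length(lines) - pos))
      vlines <- lines[pos + seq_len(n)]
      if (n > 0) {
        nfield <- lengths(strsplit(trimws(vlines), "[ \t]+"))
        bad <- which(nfield != length(velem$props))
        if (length(bad))
          stop(sprintf("malformed PLY: vertex line %d has %d fields, expected %d",
                       bad[1], nfield[bad[1]], length(velem$props)))
        vals <- scan(text = paste(vlines, collapse = "\n"), what = numeric(),
                     quiet = TRUE)
        mat <- matrix(vals, nrow = n, byrow = TRUE)
        cols <- setNames(lapply(seq_along(pnames), function(j) mat[, j]), pnames)
      } else {
        cols <- setNames(rep(list(numeric(0)), length(pnames)), pnames)
      }
      pos <- pos + n
    } else {
      pos <- pos + elem$count  # skip (e.g. faces); one record per line
    }
  }
  cols
}

.ply_read_binary <- function(raw, payload_start, hdr, velem, pnames, size) {
  offset <- payload_start
  for (elem in hdr$elements) {
    has_list <- any(vapply(elem$props, `[[`, TRUE, "list"))
    if (elem$name == "vertex") {
      if (has_list)
        stop("unsupported PLY layout: list property inside vertex element")
      sizes <- vapply(elem$props, function(p) .ply_type_size[[p$type]], 1L)
      stride <- sum(sizes)
      need <- offset + as.double(stride) * elem$count
      if (need > size)
        stop(sprintf("truncated PLY: payload ends at byte %d, need %d bytes",
                     size, need))
      offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
      cols <- setNames(lapply(seq_along(elem$props), function(j) {
        if (elem$count == 0) return(numeric(0))
        .ply_read_column(raw, offset, stride, offs[j], elem$props[[j]]$type,
                         elem$count)
      }), pnames)
      return(cols)
    }
    if (has_list)
      stop("unsupported PLY layout: list-property element precedes vertex element")
    stride <- sum(vapply(elem$props, function(p) .ply_type_size[[p$type]], 1L))
    offset <- offset + stride * elem$count
  }
  stop("malformed PLY: vertex element not found in payload walk")
}

#' Write a point cloud to PLY
#'
#' Emits a standard-conformant PLY 1.0 file readable by [read_ply()].
#' Coordinates and normals are stored as `double` so binary round trips are
#' bit-exact; colors as `uchar`.
#'
#' @param cloud a [point_cloud()].
#' @param path output file path.
#' @param binary write `binary_little_endian` (default) or ascii.
#' @return Invisibly, `path`.
#' @export
write_ply <- function(cloud, path, binary = TRUE) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  has_nrm <- !is.null(cloud$normals)
  has_col <- !is.null(cloud$colors)
  header <- c("ply",
              sprintf("format %s 1.0",
                      if (binary) "binary_little_endian" else "ascii"),
              "comment written by bunch3d",
              sprintf("element vertex %d", n),
              "property double x", "property double y", "property double z",
              if (has_nrm) c("property double nx", "property double ny",
                             "property double nz"),
              if (has_col) c("property uchar red", "property uchar green",
                             "property uchar blue"),
              "end_header")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (n == 0) return(invisible(path))
  if (!binary) {
    rows <- apply(cloud$points, 1, function(r) paste(sprintf("%.17g", r),
                                                     collapse = " "))
    if (has_nrm)
      rows <- paste(rows, apply(cloud$normals, 1, function(r)
        paste(sprintf("%.17g", r), collapse = " ")))
    if (has_col)
      rows <- paste(rows, apply(cloud$colors, 1, paste, collapse = " "))
    writeLines(rows, con, sep = "\n")
  } else {
    ncol_d <- 3L + if (has_nrm) 3L else 0L
    dbl <- cloud$points
    if (has_nrm) dbl <- cbind(dbl, cloud$normals)
    stride <- 8L * ncol_d + if (has_col) 3L else 0L
    out <- raw(n * stride)
    dbl_bytes <- writeBin(as.vector(t(dbl)), raw(), size = 8,
                          endian = "little")
    # interleave: doubles first, then the 3 color bytes per record
    idx <- as.vector(outer(seq_len(8L * ncol_d), (seq_len(n) - 1L) * stride, "+"))
    out[idx] <- dbl_bytes
    if (has_col) {
      col_bytes <- writeBin(as.integer(t(cloud$colors)), raw(), size = 1)
      idx <- as.vector(outer(8L * ncol_d + seq_len(3L),
                             (seq_len(n) - 1L) * stride, "+"))
      out[idx] <- col_bytes
    }
    writeBin(out, con)
  }
  invisible(path)
}
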