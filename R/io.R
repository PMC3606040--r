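#' Read reflection data
#'
#' Reads aligned (F_obs, F_calc, F_mask) reflection data from either the
#' columnar text dialect written by [write_reflections()] (columns
#' `h k l f_obs f_calc_re f_calc_im f_mask_re f_mask_im`, tab-separated,
#' `#`-prefixed header carrying cell and symmetry) or an mmCIF `refln`
#' loop.  Phases in text formats are always degrees.
#'
#' Friedel mates are merged on read (F_obs averaged, model columns taken
#' from the stored representative with conjugation) unless
#' `merge_friedel = FALSE`, since the scaling model is Friedel-symmetric.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"cif"`.
#' @param binding For mmCIF: named list with entries `f_obs` (one label)
#'   and `f_calc`, `f_mask` (each either two amplitude+phase labels or
#'   two real/imaginary labels ending in `_re`/`_im`).  Defaults to the
#'   PDB exchange labels `_refln.F_meas_au`,
#'   `_refln.F_calc_au`/`_refln.phase_calc` and
#'   `_refln.pdbx_F_calc_part_solvent`/`_refln.pdbx_phase_calc_part_solvent`.
#' @param cell,symmetry Optional overrides for the file header values.
#' @param merge_friedel Merge (h,k,l) with (-h,-k,-l) on read.
#' @return A [scaling_inputs()] object.
#' @export
read_reflections <- function(path, format = c("auto", "tsv", "cif"),
                             binding = NULL, cell = NULL, symmetry = NULL,
                             merge_friedel = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "tsv"
  }
  parsed <- if (format == "tsv") read_reflections_tsv(path)
            else read_reflections_cif(path, binding)
  if (!is.null(cell)) parsed$cell <- cell
  if (!is.null(symmetry)) parsed$symmetry <- symmetry
  if (is.null(parsed$cell))
    stop("no unit cell in file header; supply `cell`")
  if (is.null(parsed$symmetry)) parsed$symmetry <- "triclinic"
  df <- parsed$data
  if (nrow(df) == 0L) stop("empty reflection file")
  bad <- !is.finite(df$f_obs) | df$f_obs < 0
  if (any(bad)) {
    message(sprintf("read_reflections: dropping %d reflections with missing or negative F_obs", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  if (merge_friedel) df <- merge_friedel_mates(df)
  refl <- reflection_set(as.matrix(df[, c("h", "k", "l")]), parsed$cell,
                         parsed$symmetry)
  scaling_inputs(refl, df$f_obs,
                 complex(real = df$f_calc_re, imaginary = df$f_calc_im),
                 complex(real = df$f_mask_re, imaginary = df$f_mask_im))
}

read_reflections_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty reflection file")
  hdr <- grep("^#", lines, value = TRUE)
  cell <- NULL
  symmetry <- NULL
  cl <- grep("^#\\s*cell:", hdr, value = TRUE)
  if (length(cl) >= 1L) {
    v <- as.numeric(strsplit(trimws(sub("^#\\s*cell:", "", cl[1])),
                             "[[:space:]]+")[[1]])
    if (length(v) == 6L) cell <- unit_cell(v[1], v[2], v[3], v[4], v[5], v[6])
  }
  sy <- grep("^#\\s*symmetry:", hdr, value = TRUE)
  if (length(sy) >= 1L) symmetry <- trimws(sub("^#\\s*symmetry:", "", sy[1]))
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t", check.names = FALSE)
  need <- c("h", "k", "l", "f_obs", "f_calc_re", "f_calc_im",
            "f_mask_re", "f_mask_im")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop(sprintf("missing columns in reflection file: %s",
                 paste(miss, collapse = ", ")))
  list(data = df[, need], cell = cell, symmetry = symmetry)
}

# minimal mmCIF reader for cell items and one refln loop
read_reflections_cif <- function(path, binding = NULL) {
  if (is.null(binding))
    binding <- list(
      f_obs = "_refln.F_meas_au",
      f_calc = c("_refln.F_calc_au", "_refln.phase_calc"),
      f_mask = c("_refln.pdbx_F_calc_part_solvent",
                 "_refln.pdbx_phase_calc_part_solvent"))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  kv <- function(tag) {
    hit <- grep(paste0("^\\s*", tag, "\\s"), lines, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    gsub("^'|'$", "", trimws(sub(paste0("^\\s*", tag, "\\s+"), "", hit[1])))
  }
  cell <- NULL
  la <- kv("_cell.length_a"); lb <- kv("_cell.length_b"); lc <- kv("_cell.length_c")
  if (!is.null(la) && !is.null(lb) && !is.null(lc)) {
    aa <- kv("_cell.angle_alpha"); ab <- kv("_cell.angle_beta")
    ag <- kv("_cell.angle_gamma")
    cell <- unit_cell(as.numeric(la), as.numeric(lb), as.numeric(lc),
                      as.numeric(if (is.null(aa)) 90 else aa),
                      as.numeric(if (is.null(ab)) 90 else ab),
                      as.numeric(if (is.null(ag)) 90 else ag))
  }
  symmetry <- kv("_symmetry.space_group_name_H-M")
  if (is.null(symmetry)) symmetry <- kv("_space_group.name_H-M_alt")

  # locate the refln loop
  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  tags <- character(0); body <- character(0)
  for (ls in loop_starts) {
    i <- ls + 1L
    tg <- character(0)
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tg <- c(tg, trimws(lines[i]))
      i <- i + 1L
    }
    if (!any(grepl("^_refln\\.", tg))) next
    j <- i
    while (j <= length(lines) && !grepl("^\\s*(loop_|_|data_)", lines[j]) &&
           nzchar(trimws(lines[j]))) j <- j + 1L
    tags <- tg
    body <- lines[i:(j - 1L)]
    break
  }
  if (length(tags) == 0L) stop("no _refln loop found in mmCIF file")
  fields <- utils::read.table(text = body, header = FALSE,
                              stringsAsFactors = FALSE)
  if (ncol(fields) != length(tags))
    stop("malformed refln loop: field count does not match tag count")
  names(fields) <- tags
  get_col <- function(tag) {
    if (!tag %in% names(fields))
      stop(sprintf("mmCIF file is missing required column '%s'", tag))
    suppressWarnings(as.numeric(gsub("^[?.]$", "NA", fields[[tag]])))
  }
  as_complex <- function(labels) {
    a <- get_col(labels[1]); b <- get_col(labels[2])
    if (grepl("_im$", labels[2]) || grepl("_re$", labels[1])) {
      complex(real = a, imaginary = b)
    } else {
      complex(modulus = a, argument = b * pi / 180)   # amplitude + phase(deg)
    }
  }
  df <- data.frame(
    h = get_col("_refln.index_h"),
    k = get_col("_refln.index_k"),
    l = get_col("_refln.index_l"),
    f_obs = get_col(binding$f_obs))
  fcv <- as_complex(binding$f_calc)
  fmv <- as_complex(binding$f_mask)
  df$f_calc_re <- Re(fcv); df$f_calc_im <- Im(fcv)
  df$f_mask_re <- Re(fmv); df$f_mask_im <- Im(fmv)
  list(data = df, cell = cell, symmetry = symmetry)
}

merge_friedel_mates <- function(df) {
  flip <- df$l < 0 | (df$l == 0 & df$k < 0) |
    (df$l == 0 & df$k == 0 & df$h < 0)
  df$h[flip] <- -df$h[flip]
  df$k[flip] <- -df$k[flip]
  df$l[flip] <- -df$l[flip]
  df$f_calc_im[flip] <- -df$f_calc_im[flip]
  df$f_mask_im[flip] <- -df$f_mask_im[flip]
  key <- paste(df$h, df$k, df$l)
  if (!anyDuplicated(key)) return(df)
  fo <- tapply(df$f_obs, key, mean)
  first <- df[!duplicated(key), , drop = FALSE]
  first$f_obs <- as.numeric(fo[paste(first$h, first$k, first$l)])
  first
}

#' Write reflection data in the columnar text dialect
#'
#' @param inputs A [scaling_inputs()].
#' @param path Output path.
#' @param symmetry_label Symbol recorded in the header (default
#'   `"triclinic"`); [reflection_set()] stores rotations, not symbols,
#'   so the label must be supplied for a lossless round trip.
#' @return `path`, invisibly.
#' @export
write_reflections <- function(inputs, path, symmetry_label = "triclinic") {
  stopifnot(inherits(inputs, "scaling_inputs"))
  cell <- inputs$refl$cell
  num <- function(x) sprintf("%.17g", x)
  hdr <- c("# bulksolv reflections 1",
           paste("# cell:", paste(num(c(cell$a, cell$b, cell$c, cell$alpha,
                                        cell$beta, cell$gamma)),
                                  collapse = " ")),
           paste("# symmetry:", symmetry_label),
           paste(c("h", "k", "l", "f_obs", "f_calc_re", "f_calc_im",
                   "f_mask_re", "f_mask_im"), collapse = "\t"))
  h <- inputs$refl$indices
  rows <- paste(h[, 1], h[, 2], h[, 3],
                num(inputs$f_obs),
                num(Re(inputs$f_calc)), num(Im(inputs$f_calc)),
                num(Re(inputs$f_mask)), num(Im(inputs$f_mask)),
                sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a scaling result as JSON
#'
#' Serializes the scalar results, per-bin table and convergence trace
#' with stable key order (schema 1); floats carry 12 significant
#' digits.  Optionally writes a per-reflection TSV of the scale
#' components.
#'
#' @param result A `scaling_result` from [run_scaling()].
#' @param path Output JSON path.
#' @param per_reflection_path Optional TSV path for per-reflection
#'   k components.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, per_reflection_path = NULL) {
  stopifnot(inherits(result, "scaling_result"))
  tbl <- result$bins$table
  out <- list(
    schema = 1L,
    r_all = result$r_all,
    r_low = as.numeric(result$r_low),
    r_high = as.numeric(result$r_high),
    k_overall = result$k_overall,
    cycles = result$cycles,
    trace = as.numeric(result$trace),
    aniso_method = result$aniso$method,
    aniso = result$aniso[setdiff(names(result$aniso), "method")],
    solvent_fit = result$solvent_fit,
    overall_fit = result$overall_fit,
    twin_fractions = if (is.null(result$twin)) NULL else
      as.numeric(result$twin$fractions),
    n_excluded = result$n_excluded,
    bins = as.list(tbl))
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = I(12),
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  if (!is.null(per_reflection_path)) {
    df <- data.frame(
      d = result$d,
      bin = result$bin_of,
      f_obs = result$f_obs,
      f_model = result$f_model,
      k_total = result$k_total,
      k_isotropic = result$k_isotropic,
      k_anisotropic = result$k_anisotropic,
      k_mask = result$k_mask)
    utils::write.table(format(df, digits = 12, trim = TRUE),
                       per_reflection_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
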