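#' Construct a label lookup table
#'
#' @param table data.frame with columns `id`, `name`, `region`, `partner`,
#'   `r`, `g`, `b`.
#' @return a [LabelLookup-class].
#' @export
LabelLookup <- function(table) {
  table$id <- as.integer(table$id)
  table$partner <- as.integer(table$partner)
  new("LabelLookup", table = table)
}

#' The default 24-structure hypothalamic lookup table
#'
#' Hypothalamic sub-regions (anterior, middle, posterior), optic
#' structures and adjacent structures. Nine lateral pairs (L-/R-) plus six
#' midline structures give 24 labels, which merge to 15 classes in the
#' sagittal view where lateralization is not visible.
#'
#' @return a [LabelLookup-class] with 24 entries.
#' @export
hypothalamusLUT <- function() {
  e <- function(id, name, region, partner, r, g, b)
    data.frame(id = id, name = name, region = region, partner = partner,
               r = r, g = g, b = b)
  tb <- rbind(
    e(1L,  "L-Ant-Hypothalamus",  "hypothalamic-anterior",  2L,  255,  80,  80),
    e(2L,  "R-Ant-Hypothalamus",  "hypothalamic-anterior",  1L,  205,  40,  40),
    e(3L,  "L-Med-Hypothalamus",  "hypothalamic-middle",    4L,  255, 160,  60),
    e(4L,  "R-Med-Hypothalamus",  "hypothalamic-middle",    3L,  205, 120,  30),
    e(5L,  "L-Lat-Hypothalamus",  "hypothalamic-middle",    6L,  250, 220,  60),
    e(6L,  "R-Lat-Hypothalamus",  "hypothalamic-middle",    5L,  200, 180,  30),
    e(7L,  "Tuberal-region",      "hypothalamic-middle",    NA,  170, 255,  60),
    e(8L,  "L-Post-Hypothalamus", "hypothalamic-posterior", 9L,   80, 220,  80),
    e(9L,  "R-Post-Hypothalamus", "hypothalamic-posterior", 8L,   40, 170,  40),
    e(10L, "L-C-Mammilare",       "hypothalamic-posterior", 11L,  60, 230, 200),
    e(11L, "R-C-Mammilare",       "hypothalamic-posterior", 10L,  30, 180, 155),
    e(12L, "3rd-Ventricle",       "others",                 NA,   90, 140, 255),
    e(13L, "L-Fornix",            "others",                 14L, 150,  90, 255),
    e(14L, "R-Fornix",            "others",                 13L, 110,  50, 205),
    e(15L, "Epiphysis",           "others",                 NA,  255,  90, 220),
    e(16L, "Hypophysis",          "others",                 NA,  255, 150, 200),
    e(17L, "Infundibulum",        "others",                 NA,  200, 110, 160),
    e(18L, "Ant-Commisure",       "others",                 NA,  130, 130, 130),
    e(19L, "L-N-Opticus",         "optic",                  20L,  60, 100, 200),
    e(20L, "R-N-Opticus",         "optic",                  19L,  30,  70, 160),
    e(21L, "L-Chiasma-Opticus",   "optic",                  22L, 100, 200, 250),
    e(22L, "R-Chiasma-Opticus",   "optic",                  21L,  60, 160, 210),
    e(23L, "L-Optic-tract",       "optic",                  24L,  20, 120, 120),
    e(24L, "R-Optic-tract",       "optic",                  23L,  10,  80,  80))
  LabelLookup(tb)
}

#' A 6-label toy lookup table for desk-scale phantoms
#'
#' One midline ventricle-like structure, one midline commissure-like rod,
#' a lateral pair of nucleus-like spheres and a lateral pair of tube-like
#' optic structures: 6 labels with 2 partner pairs, merging to 4 sagittal
#' classes.
#'
#' @return a [LabelLookup-class] with 6 entries.
#' @export
toyLUT <- function() {
  tb <- data.frame(
    id = 1:6,
    name = c("Ventricle", "L-Nucleus", "R-Nucleus",
             "L-Optic-tube", "R-Optic-tube", "Commissure"),
    region = c("others", "hypothalamic-middle", "hypothalamic-middle",
               "optic", "optic", "others"),
    partner = c(NA, 3L, 2L, 5L, 4L, NA),
    r = c(90, 255, 205, 20, 10, 130),
    g = c(140, 80, 40, 120, 80, 130),
    b = c(255, 80, 40, 120, 80, 130))
  LabelLookup(tb)
}

#' Merge lateral label pairs for the sagittal view
#'
#' Collapses every symmetric L-/R- partner pair onto one merged class (the
#' merged entry keeps the lower id and the side-stripped name); unpaired
#' labels map to themselves. With the shipped 24-entry table this yields
#' 15 classes.
#'
#' @param lut a [LabelLookup-class].
#' @return list with `merged` (a [LabelLookup-class]) and `mapping`, a
#'   named integer vector from original id to merged id.
#' @export
mergeLateralLabels <- function(lut) {
  tb <- lutTable(lut)
  mapping <- tb$id
  names(mapping) <- tb$id
  keep <- rep(TRUE, nrow(tb))
  for (i in seq_len(nrow(tb))) {
    p <- tb$partner[i]
    if (is.na(p)) next
    j <- match(p, tb$id)
    lo <- min(tb$id[i], tb$id[j])
    mapping[as.character(tb$id[i])] <- lo
    if (tb$id[i] > lo) keep[i] <- FALSE
  }
  mtb <- tb[keep, , drop = FALSE]
  mtb$name <- .strip_side(mtb$name)
  mtb$partner <- NA_integer_
  rownames(mtb) <- NULL
  list(merged = LabelLookup(mtb), mapping = mapping)
}

#' Read / write lookup tables
#'
#' FreeSurfer-style color table text (`id name R G B A`) extended with two
#' sidecar columns, `region` and `partner` (0 for none).
#'
#' @param path file path.
#' @return [LabelLookup-class] for `readLUT`; invisible path for
#'   `writeLUT`.
#' @export
readLUT <- function(path) {
  if (!file.exists(path)) .stopf("ioError", "LUT file not found: %s", path)
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  parts <- strsplit(trimws(ln), "\\s+")
  bad <- vapply(parts, length, 1L) != 8L
  if (any(bad)) .stopf("lutError", "malformed LUT line: %s", ln[which(bad)[1]])
  m <- do.call(rbind, parts)
  partner <- as.integer(m[, 8])
  LabelLookup(data.frame(
    id = as.integer(m[, 1]), name = m[, 2], region = m[, 7],
    partner = ifelse(partner == 0L, NA_integer_, partner),
    r = as.integer(m[, 3]), g = as.integer(m[, 4]), b = as.integer(m[, 5])))
}

#' @rdname readLUT
#' @param lut a [LabelLookup-class].
#' @export
writeLUT <- function(lut, path) {
  tb <- lutTable(lut)
  ln <- sprintf("%d\t%s\t%d\t%d\t%d\t0\t%s\t%d", tb$id, tb$name,
                tb$r, tb$g, tb$b, tb$region,
                ifelse(is.na(tb$partner), 0L, tb$partner))
  writeLines(c("# id name R G B A region partner", ln), path)
  invisible(path)
}

#' Apply a label mapping to a LABEL volume
#'
#' @param vol a `LABEL` [BrainVolume-class].
#' @param mapping named integer vector as returned by
#'   [mergeLateralLabels()]; background 0 always maps to 0.
#' @return relabelled [BrainVolume-class].
#' @export
applyLabelMapping <- function(vol, mapping) {
  if (modality(vol) != "LABEL")
    .stopf("modalityError", "expected a LABEL volume")
  x <- volData(vol)
  out <- x
  for (id in names(mapping)) out[x == as.integer(id)] <- mapping[[id]]
  new("BrainVolume", data = out, voxelSize = voxelSize(vol),
      affine = vol@affine, modality = "LABEL")
}
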