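#' Panel container for a DEA input-output system
#'
#' Holds a balanced units-by-years panel of strictly positive inputs,
#' desirable outputs and undesirable outputs, the raw material for frontier
#' scoring. Values are stored as three-dimensional arrays (variable, unit,
#' year) so that each calendar year provides one cross-sectional frontier.
#'
#' @param x numeric array of inputs, dim \code{c(m, n, T)}, or a matrix
#'   (single year). Row names label the inputs.
#' @param y numeric array of desirable outputs, dim \code{c(s, n, T)}.
#' @param u numeric array of undesirable outputs, dim \code{c(q, n, T)}, or
#'   \code{NULL} for a model without undesirable outputs.
#' @param units character vector of unit labels (length n).
#' @param years integer vector of years (length T).
#' @return An object of class \code{dea_panel}.
#' @export
dea_panel <- function(x, y, u = NULL, units = NULL, years = NULL) {
  as_cube <- function(a, what) {
    if (is.matrix(a)) a <- array(a, c(nrow(a), ncol(a), 1L),
                                 dimnames = c(dimnames(a), list(NULL)))
    if (!is.array(a) || length(dim(a)) != 3L)
      stop(what, " must be a (variable x unit x year) array or a matrix")
    storage.mode(a) <- "double"
    a
  }
  x <- as_cube(x, "x"); y <- as_cube(y, "y")
  n <- dim(x)[2]; nT <- dim(x)[3]
  if (is.null(units)) units <- dimnames(x)[[2]]
  if (is.null(units)) units <- paste0("U", seq_len(n))
  if (is.null(years)) years <- dimnames(x)[[3]]
  if (is.null(years)) years <- seq_len(nT)
  years <- as.integer(years)
  if (!is.null(u)) u <- as_cube(u, "u")
  for (a in list(x = x, y = y, u = u)) {
    if (is.null(a)) next
    if (dim(a)[2] != n || dim(a)[3] != nT)
      stop("x, y and u must share unit and year dimensions")
    if (anyNA(a)) stop("panel contains missing cells; complete it first ",
                       "(see interpolate_missing)")
    if (any(a <= 0)) stop("all panel values must be strictly positive")
  }
  name_cube <- function(a, pre) {
    if (is.null(a)) return(NULL)
    if (is.null(dimnames(a)[[1]]))
      dimnames(a)[[1]] <- paste0(pre, seq_len(dim(a)[1]))
    dimnames(a)[[2]] <- units; dimnames(a)[[3]] <- as.character(years)
    a
  }
  structure(list(x = name_cube(x, "x"), y = name_cube(y, "y"),
                 u = name_cube(u, "u"),
                 units = units, years = years),
            class = "dea_panel")
}

#' @export
print.dea_panel <- function(x, ...) {
  q <- if (is.null(x$u)) 0L else dim(x$u)[1]
  cat(sprintf(
    "DEA panel: %d units x %d years; %d inputs, %d desirable, %d undesirable outputs\n",
    length(x$units), length(x$years), dim(x$x)[1], dim(x$y)[1], q))
  invisible(x)
}

#' @export
dim.dea_panel <- function(x)
  c(m = dim(x$x)[1], s = dim(x$y)[1],
    q = if (is.null(x$u)) 0L else dim(x$u)[1],
    n = length(x$units), T = length(x$years))

#' Extract one cross-section (year) of a DEA panel
#'
#' @param panel a \code{dea_panel}.
#' @param year calendar year (matched against \code{panel$years}) or index.
#' @return list with matrices \code{x} (m x n), \code{y} (s x n) and
#'   \code{u} (q x n or NULL).
#' @export
panel_year <- function(panel, year) {
  stopifnot(inherits(panel, "dea_panel"))
  i <- if (year %in% panel$years) match(year, panel$years) else year
  if (is.na(i) || i < 1L || i > length(panel$years))
    stop("year ", year, " not present in panel")
  slice <- function(a) {
    if (is.null(a)) return(NULL)
    m <- matrix(a[, , i], dim(a)[1], dim(a)[2])
    dimnames(m) <- dimnames(a)[1:2]
    m
  }
  list(x = slice(panel$x), y = slice(panel$y), u = slice(panel$u))
}

# Default column-role schema for long-format panel CSV files. Roles follow
# the health-production input-output system: four inputs, one desirable
# output, two undesirable outputs, six covariates.
#' @rdname load_panel
#' @export
default_schema <- function() {
  list(unit = "unit", year = "year",
       inputs = c("K_e", "K_i", "K_b", "I"),
       outputs = "y",
       bads = c("B_w", "B_m"),
       covariates = c("Pgdp", "Urb", "Med", "Mnm", "Gov", "Pd"))
}

#' Read a long-format unit-year panel from CSV
#'
#' One row per unit-year; the schema maps column roles (unit, year, inputs,
#' desirable outputs, undesirable outputs, covariates) onto column names.
#' Rows are normalised to unit-then-year order; covariate columns are
#' optional as a block but, when named by the schema, must all be present.
#'
#' @param path CSV file path.
#' @param schema named list with entries \code{unit}, \code{year},
#'   \code{inputs}, \code{outputs}, \code{bads}, \code{covariates};
#'   see \code{default_schema()}.
#' @return list with components \code{panel} (a \code{dea_panel}) and
#'   \code{covariates} (data frame with unit, year and covariate columns,
#'   or \code{NULL} when the schema lists none).
#' @export
load_panel <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  need <- c(schema$unit, schema$year, schema$inputs, schema$outputs,
            schema$bads)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "))
  # covariates are optional as a block, but a partial block is an error
  has_cov <- intersect(schema$covariates, names(d))
  if (length(has_cov) && length(has_cov) < length(schema$covariates))
    stop("schema error: missing required column(s): ",
         paste(setdiff(schema$covariates, has_cov), collapse = ", "))
  schema$covariates <- has_cov
  key <- paste(d[[schema$unit]], d[[schema$year]])
  if (anyDuplicated(key))
    stop("integrity error: duplicate unit-year row(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  d <- d[order(d[[schema$unit]], d[[schema$year]]), , drop = FALSE]
  units <- unique(d[[schema$unit]]); years <- sort(unique(d[[schema$year]]))
  if (nrow(d) != length(units) * length(years))
    stop("integrity error: panel is not balanced (", nrow(d), " rows for ",
         length(units), " units x ", length(years), " years)")
  # after sorting by (unit, year), d is unit-major: each unit's years are
  # contiguous, so a years-by-units matrix fills column-wise
  cube <- function(cols) {
    a <- array(NA_real_, c(length(cols), length(units), length(years)),
               dimnames = list(cols, units, as.character(years)))
    for (j in seq_along(cols)) {
      m <- matrix(d[[cols[j]]], nrow = length(years), ncol = length(units))
      a[j, , ] <- t(m)
    }
    a
  }
  pan <- dea_panel(cube(schema$inputs), cube(schema$outputs),
                   if (length(schema$bads)) cube(schema$bads) else NULL,
                   units = units, years = years)
  cov <- NULL
  if (length(schema$covariates)) {
    cov <- d[, c(schema$unit, schema$year, schema$covariates), drop = FALSE]
    names(cov)[1:2] <- c("unit", "year")
    rownames(cov) <- NULL
  }
  list(panel = pan, covariates = cov)
}

#' Write a DEA panel (and covariates) to long-format CSV
#'
#' Inverse of \code{load_panel}: one row per unit-year, columns named by the
#' schema.
#'
#' @param panel a \code{dea_panel}.
#' @param path output CSV path.
#' @param covariates optional data frame with unit, year and covariate
#'   columns as produced by \code{load_panel} or \code{generate_sdm_panel}.
#' @param schema column-role mapping, see \code{default_schema()}.
#' @return \code{path}, invisibly.
#' @export
write_panel_csv <- function(panel, path, covariates = NULL,
                            schema = default_schema()) {
  stopifnot(inherits(panel, "dea_panel"))
  units <- panel$units; years <- panel$years
  grid <- expand.grid(year = years, unit = units,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("unit", "year")]
  out <- data.frame(grid, check.names = FALSE)
  names(out) <- c(schema$unit, schema$year)
  put <- function(a, cols) {
    for (j in seq_along(cols))
      out[[cols[j]]] <<- as.vector(t(a[j, , ]))  # unit-major, year-minor
  }
  put(panel$x, schema$inputs); put(panel$y, schema$outputs)
  if (!is.null(panel$u)) put(panel$u, schema$bads)
  if (!is.null(covariates)) {
    key <- paste(out[[schema$unit]], out[[schema$year]])
    ck <- paste(covariates$unit, covariates$year)
    for (v in setdiff(names(covariates), c("unit", "year")))
      out[[v]] <- covariates[[v]][match(key, ck)]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Perinatal survival rate from perinatal mortality rate
#'
#' The desirable output of the health production system: survival is one
#' minus the perinatal mortality rate, both expressed as proportions.
#'
#' @param mortality_rate proportion(s) in \code{[0, 1]}.
#' @return \code{1 - mortality_rate}.
#' @export
perinatal_survival <- function(mortality_rate) {
  if (any(!is.finite(mortality_rate)) ||
      any(mortality_rate < 0 | mortality_rate > 1))
    stop("mortality_rate must lie in [0, 1]")
  1 - mortality_rate
}

#' Complete a series with interior and edge gaps
#'
#' Interior gaps are filled by linear interpolation between the nearest
#' observed neighbours; gaps at the start or end of the series take the
#' nearest observed value. Observed values are never altered, so the
#' operation is idempotent.
#'
#' @param series numeric vector, gaps as \code{NA}.
#' @return completed numeric vector.
#' @export
interpolate_missing <- function(series) {
  obs <- which(!is.na(series))
  if (length(obs) == 0L) stop("cannot complete an all-missing series")
  if (length(obs) == length(series)) return(series)
  if (length(obs) == 1L) return(rep(series[obs], length(series)))
  out <- stats::approx(obs, series[obs], xout = seq_along(series),
                       method = "linear", rule = 2)$y
  out[obs] <- series[obs]
  out
}

# Region membership of the 31 provincial units under the National Bureau of
# Statistics four-region economic scheme (10 Eastern, 6 Middle, 12 Western,
# 3 Northeastern), keyed by pinyin labels.
.china_nbs_regions <- c(
  BeiJing = "Eastern", TianJin = "Eastern", HeBei = "Eastern",
  GuangDong = "Eastern", HaiNan = "Eastern", ShangHai = "Eastern",
  JiangSu = "Eastern", ZheJiang = "Eastern", FuJian = "Eastern",
  ShanDong = "Eastern",
  ShanXi = "Middle", AnHui = "Middle", JiangXi = "Middle",
  HeNan = "Middle", HuBei = "Middle", HuNan = "Middle",
  GuangXi = "Western", ChongQing = "Western", SiChuan = "Western",
  GuiZhou = "Western", YunNan = "Western", XiZang = "Western",
  ShaanXi = "Western", GanSu = "Western", QingHai = "Western",
  NingXia = "Western", XinJiang = "Western", NeiMengGu = "Western",
  LiaoNing = "Northeastern", JiLin = "Northeastern",
  HeiLongJiang = "Northeastern")

#' Assign units to regions
#'
#' Returns a total partition of the units into region labels. The packaged
#' \code{"china_nbs"} scheme divides the 31 provincial units into Eastern,
#' Middle, Western and Northeastern regions (sizes 10/6/12/3).
#'
#' @param unit_ids character vector of unit labels.
#' @param scheme either the name of a packaged scheme (\code{"china_nbs"})
#'   or a named character vector mapping unit label to region label.
#' @return named character vector (unit -> region), class
#'   \code{region_scheme}.
#' @export
assign_regions <- function(unit_ids, scheme = "china_nbs") {
  map <- if (is.character(scheme) && length(scheme) == 1L &&
             is.null(names(scheme))) {
    if (scheme != "china_nbs") stop("unknown region scheme: ", scheme)
    .china_nbs_regions
  } else {
    if (is.null(names(scheme))) stop("user scheme must be a named vector")
    scheme
  }
  miss <- setdiff(unit_ids, names(map))
  if (length(miss))
    stop("unmapped unit(s): ", paste(miss, collapse = ", "))
  structure(map[unit_ids], class = "region_scheme")
}

#' Efficiency score table
#'
#' Units-by-years grid of efficiency scores with optional region labels and
#' optional TE/PTE/SE companion grids from the CRS/VRS decomposition.
#'
#' @param scores numeric matrix, units in rows, years in columns.
#' @param regions optional named region vector (see
#'   \code{\link{assign_regions}}).
#' @param te,pte,se optional companion matrices of identical shape.
#' @return object of class \code{efficiency_table}.
#' @export
efficiency_table <- function(scores, regions = NULL, te = NULL, pte = NULL,
                             se = NULL) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("U", seq_len(nrow(scores)))
  if (any(scores <= 0, na.rm = TRUE)) stop("efficiency scores must be > 0")
  if (!is.null(regions)) {
    regions <- assign_regions(rownames(scores), regions)
  }
  structure(list(scores = scores, regions = regions,
                 te = te, pte = pte, se = se),
            class = "efficiency_table")
}

#' @export
print.efficiency_table <- function(x, digits = 3, ...) {
  cat(sprintf("Efficiency table: %d units x %d years\n",
              nrow(x$scores), ncol(x$scores)))
  s <- utils::head(summary(x), 10)
  num <- vapply(s, is.numeric, logical(1))
  s[num] <- lapply(s[num], round, digits)
  print(s)
  if (nrow(s) > 10) cat("... ", nrow(s) - 10, " more units\n", sep = "")
  invisible(x)
}

#' @export
summary.efficiency_table <- function(object, ...) {
  s <- object$scores
  out <- data.frame(s, check.names = FALSE)
  out$max <- apply(s, 1, max, na.rm = TRUE)
  out$min <- apply(s, 1, min, na.rm = TRUE)
  out$mean <- rowMeans(s, na.rm = TRUE)
  if (!is.null(object$regions)) out$region <- unname(object$regions)
  out
}

#' @export
as.data.frame.efficiency_table <- function(x, ...) {
  d <- expand.grid(unit = rownames(x$scores), year = colnames(x$scores),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$score <- as.vector(x$scores)
  if (!is.null(x$regions)) d$region <- unname(x$regions[d$unit])
  d
}

#' Regional aggregation of an efficiency table
#'
#' Unweighted arithmetic aggregate (mean, max or min) of member-unit scores
#' per region. No rounding is applied; round only for presentation.
#'
#' @param table an \code{efficiency_table}.
#' @param scheme region scheme (see \code{\link{assign_regions}}); defaults
#'   to the table's own region labels.
#' @param stat one of \code{"mean"}, \code{"max"}, \code{"min"}.
#' @param year single year (column label or index), or \code{NULL} for all
#'   years.
#' @return data frame with columns \code{region}, \code{year},
#'   \code{value}.
#' @export
aggregate_regional <- function(table, scheme = NULL,
                               stat = c("mean", "max", "min"),
                               year = NULL) {
  stopifnot(inherits(table, "efficiency_table"))
  stat <- match.arg(stat)
  regions <- if (is.null(scheme)) table$regions
             else assign_regions(rownames(table$scores), scheme)
  if (is.null(regions)) stop("no region scheme available")
  f <- switch(stat, mean = mean, max = max, min = min)
  s <- table$scores
  cols <- if (is.null(year)) colnames(s) else {
    yc <- as.character(year)
    if (!yc %in% colnames(s)) stop("year ", year, " not in table")
    yc
  }
  out <- do.call(rbind, lapply(cols, function(cl) {
    v <- tapply(s[, cl], unname(regions), f)
    if (any(is.na(v))) stop("empty region in aggregation")
    data.frame(region = names(v), year = cl, value = unname(v))
  }))
  rownames(out) <- NULL
  out
}

#' Grade an efficiency score
#'
#' Bands follow the half-open intervals (0, 0.8] low, (0.8, 1] medium and
#' above 1 high. The finer eight-grade scale refines the bands with
#' equal-width 0.1 steps between 0.6 and 1.2 and open outer intervals;
#' alternative cut points may be supplied as long as they refine the band
#' boundaries at 0.8 and 1.
#'
#' @param value positive efficiency score(s).
#' @param grade_breaks increasing interior cut points of the 8-grade scale.
#' @return data frame with columns \code{value}, \code{band} (factor:
#'   low/medium/high) and \code{grade} (integer 1..8).
#' @export
grade_efficiency <- function(value,
                             grade_breaks = seq(0.6, 1.2, by = 0.1)) {
  if (any(!is.finite(value)) || any(value <= 0))
    stop("efficiency value must be > 0")
  band <- cut(value, c(0, 0.8, 1, Inf),
              labels = c("low", "medium", "high"), right = TRUE)
  grade <- as.integer(cut(value, c(-Inf, grade_breaks, Inf), right = TRUE))
  data.frame(value = value, band = band, grade = grade)
}
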