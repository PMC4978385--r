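# Resistance surfaces and circuit-theory effective resistance.
#
# A resistance surface is a raster whose cells encode hypothesized
# impedance to gene flow on a 1 (permeable) to 100 (resistant) scale. The
# lattice of cells is treated as a resistor network: every cell is a node,
# neighboring cells are joined by a conductance equal to the mean of their
# conductances (1/resistance), diagonal neighbors down-weighted by sqrt(2);
# the two-terminal effective resistance between sampling sites summarizes
# gene-flow opportunity over all paths simultaneously.

#' Raster grid container
#'
#' Row 1 is the north edge; cell centers sit at
#' `(xll + (col - 0.5) * cellsize, yll + (nrow - row + 0.5) * cellsize)`.
#'
#' @param grid numeric matrix (NA = nodata)
#' @param cellsize cell edge length in meters
#' @param xll,yll lower-left corner of the grid (projected meters)
#' @return object of class `raster_grid`
#' @export
raster_grid <- function(grid, cellsize, xll = 0, yll = 0) {
  grid <- as.matrix(grid)
  stopifnot(cellsize > 0)
  structure(list(grid = grid, cellsize = cellsize, xll = xll, yll = yll),
            class = "raster_grid")
}

#' Read an ESRI ASCII grid
#' @param path file with ncols/nrows/xllcorner/yllcorner/cellsize/
#'   NODATA_value header followed by rows north to south
#' @return a [raster_grid()]
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("missing ASCII grid header fields in ", path)
  vals <- as.numeric(unlist(strsplit(trimws(lines[i:length(lines)]), "[ \t]+")))
  vals <- vals[!is.na(vals) | TRUE]
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid size mismatch in ", path)
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  g <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  raster_grid(g, hdr$cellsize, hdr$xllcorner, hdr$yllcorner)
}

#' Write an ESRI ASCII grid
#' @param rg a [raster_grid()]
#' @param path output path
#' @param nodata sentinel written for NA cells
#' @return `path` invisibly
#' @export
write_ascii_grid <- function(rg, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(rg$grid)),
               paste("nrows", nrow(rg$grid)),
               paste("xllcorner", rg$xll),
               paste("yllcorner", rg$yll),
               paste("cellsize", rg$cellsize),
               paste("NODATA_value", nodata)), con)
  g <- rg$grid
  g[is.na(g)] <- nodata
  writeLines(apply(g, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Build a resistance surface from a landscape layer
#'
#' Scaling follows the four gene-flow hypotheses: `distance` = uniform 1
#' everywhere (isolation by distance); `slope` = linear map of observed
#' min..max slope onto 1..100 (steep = resistant); `canopy` = linear map of
#' max..min canopy onto 1..100 (closed canopy = permeable); `stream` = 1
#' within `stream_buffer_m` of a stream cell, 100 outside.
#'
#' @param layer a [raster_grid()]: slope (degrees or percent), canopy
#'   (percent cover), or a 0/1 stream presence raster; any layer works for
#'   `distance`
#' @param model `"distance"`, `"slope"`, `"canopy"` or `"stream"`
#' @param stream_buffer_m riparian buffer radius (default 100 m)
#' @return object of class `resistance_surface` (a [raster_grid()] with a
#'   `model` tag; all data cells in \[1, 100\])
#' @export
build_surface <- function(layer, model = c("distance", "slope", "canopy",
                                           "stream"),
                          stream_buffer_m = 100) {
  model <- match.arg(model)
  g <- layer$grid
  if (model == "distance") {
    out <- ifelse(is.na(g), NA_real_, 1)
  } else if (model %in% c("slope", "canopy")) {
    rng <- range(g, na.rm = TRUE)
    if (diff(rng) == 0)
      stop("constant ", model, " layer cannot be scaled; use model='distance'")
    z <- (g - rng[1]) / diff(rng)
    if (model == "canopy") z <- 1 - z          # high canopy = low resistance
    out <- 1 + 99 * z
  } else {
    stream <- which(!is.na(g) & g > 0, arr.ind = TRUE)
    if (!nrow(stream)) stop("stream layer has no stream cells")
    rad <- floor(stream_buffer_m / layer$cellsize)
    out <- ifelse(is.na(g), NA_real_, 100)
    offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
    offs <- offs[(offs$dr^2 + offs$dc^2) * layer$cellsize^2 <=
                   stream_buffer_m^2, , drop = FALSE]
    for (o in seq_len(nrow(offs))) {
      rr <- stream[, 1] + offs$dr[o]
      cc <- stream[, 2] + offs$dc[o]
      ok <- rr >= 1 & rr <= nrow(g) & cc >= 1 & cc <= ncol(g)
      out[cbind(rr[ok], cc[ok])] <- 1
    }
    out[is.na(g)] <- NA_real_
  }
  structure(list(grid = out, cellsize = layer$cellsize, xll = layer$xll,
                 yll = layer$yll, model = model),
            class = c("resistance_surface", "raster_grid"))
}

# nearest cell (row, col) for site coordinates; errors off-grid or on nodata
.site_cells <- function(surface, sites) {
  nr <- nrow(surface$grid); ncl <- ncol(surface$grid)
  cells <- matrix(NA_integer_, nrow(sites), 2)
  for (s in seq_len(nrow(sites))) {
    col <- floor((sites$x[s] - surface$xll) / surface$cellsize) + 1
    row <- nr - floor((sites$y[s] - surface$yll) / surface$cellsize)
    if (col < 1 || col > ncl || row < 1 || row > nr)
      stop("site ", sites$site[s], " falls outside the raster extent")
    if (is.na(surface$grid[row, col]))
      stop("site ", sites$site[s], " falls on a nodata cell")
    cx <- surface$xll + (col - 0.5) * surface$cellsize
    cy <- surface$yll + (nr - row + 0.5) * surface$cellsize
    if (sqrt((cx - sites$x[s])^2 + (cy - sites$y[s])^2) >
          surface$cellsize / sqrt(2) + 1e-9)
      warning("site ", sites$site[s], " snapped more than half a cell")
    cells[s, ] <- c(row, col)
  }
  cells
}

# sparse graph Laplacian of the resistance lattice; returns list(L, index)
# where index maps (row, col) -> node id over data cells
.surface_laplacian <- function(surface, scheme = 8) {
  g <- surface$grid
  nr <- nrow(g); ncl <- ncol(g)
  idx <- matrix(NA_integer_, nr, ncl)
  data_cells <- which(!is.na(g))
  idx[data_cells] <- seq_along(data_cells)
  cond <- 1 / g
  offs <- list(c(0, 1, 1), c(1, 0, 1))
  if (scheme == 8) offs <- c(offs, list(c(1, 1, sqrt(2)), c(1, -1, sqrt(2))))
  else if (scheme != 4) stop("scheme must be 4 or 8")
  ii <- jj <- integer(0); ww <- numeric(0)
  for (o in offs) {
    r1 <- seq_len(nr - o[1])
    c1 <- if (o[2] >= 0) seq_len(ncl - o[2]) else seq(1 - o[2], ncl)
    a <- as.matrix(expand.grid(r = r1, c = c1))
    b <- cbind(a[, 1] + o[1], a[, 2] + o[2])
    na_ <- idx[a]; nb <- idx[b]
    ok <- !is.na(na_) & !is.na(nb)
    w <- (cond[a[ok, , drop = FALSE]] + cond[b[ok, , drop = FALSE]]) / 2 / o[3]
    ii <- c(ii, na_[ok]); jj <- c(jj, nb[ok]); ww <- c(ww, w)
  }
  n <- length(data_cells)
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(n, n))
  L <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W
  list(L = L, idx = idx)
}

#' Circuit-theory pairwise effective resistance between sites
#'
#' Solves the grounded graph Laplacian of the resistance lattice once per
#' site column: `R_ij = x_ii + x_jj - 2 x_ij` with `x` the solved
#' potentials. Disconnected site pairs receive `Inf` with a warning.
#'
#' @param surface a `resistance_surface`
#' @param sites data frame with `site`, `x`, `y` (projected meters)
#' @param scheme neighbor connection scheme: 8 (default) or 4
#' @return a [pairwise_matrix()] with metric `"resistance"` and attributes
#'   `scheme`, `tolerance`
#' @export
effective_resistance <- function(surface, sites, scheme = 8) {
  cells <- .site_cells(surface, sites)
  lap <- .surface_laplacian(surface, scheme)
  nodes <- lap$idx[cells]
  k <- length(nodes)
  ground <- nodes[1]
  keep <- setdiff(seq_len(nrow(lap$L)), ground)
  Lg <- lap$L[keep, keep]
  pos <- match(nodes, keep)                    # NA for the grounded site
  R <- matrix(0, k, k, dimnames = list(sites$site, sites$site))
  rhs <- Matrix::sparseMatrix(i = pos[-1], j = seq_len(k - 1), x = 1,
                              dims = c(length(keep), k - 1))
  X <- tryCatch(as.matrix(Matrix::solve(Lg, rhs)),
                error = function(e) NULL)
  if (is.null(X)) {
    warning("lattice is disconnected between some sites; Inf resistance")
    comp <- .lattice_components(lap$L)
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k))
      R[i, j] <- R[j, i] <-
        if (comp[nodes[i]] == comp[nodes[j]]) NA_real_ else Inf
    return(pairwise_matrix(R, sites$site, "resistance"))
  }
  # column c of X solves for unit current injected at site c+1 with site 1
  # grounded, so R_1i = x_ii and R_ij = x_ii + x_jj - 2 x_ij
  for (i in 2:k) {
    R[1, i] <- R[i, 1] <- X[pos[i], i - 1]
    if (i < k) for (j in seq((i + 1), k))
      R[i, j] <- R[j, i] <- X[pos[i], i - 1] + X[pos[j], j - 1] -
        2 * X[pos[i], j - 1]
  }
  m <- pairwise_matrix(R, sites$site, "resistance")
  attr(m, "scheme") <- scheme
  attr(m, "tolerance") <- 1e-10
  m
}

# connected-component labels of the lattice graph (BFS on the Laplacian)
.lattice_components <- function(L) {
  n <- nrow(L)
  comp <- integer(n)
  Lp <- as(L, "generalMatrix")
  adj <- Matrix::summary(Lp)
  adj <- adj[adj$i != adj$j, ]
  nb <- split(adj$j, adj$i)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in nb[[as.character(v)]])
        if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

#' Collinearity screen between pairwise matrices
#'
#' Pearson correlation between vectorized lower triangles; matrix pairs
#' with `|r| > threshold` are flagged as non-combinable in one model.
#'
#' @param matrices named list of [pairwise_matrix()] objects over the same
#'   sites
#' @param threshold collinearity cutoff (default 0.7)
#' @return data frame: a, b, r, collinear
#' @export
screen_collinearity <- function(matrices, threshold = 0.7) {
  k <- length(matrices)
  stopifnot(k >= 2)
  if (length(matrices[[1]]$sites) < 3)
    stop("collinearity screen needs >= 3 sites")
  nm <- names(matrices)
  if (is.null(nm)) nm <- paste0("m", seq_len(k))
  prs <- combn(k, 2)
  out <- data.frame(a = nm[prs[1, ]], b = nm[prs[2, ]],
                    r = NA_real_, stringsAsFactors = FALSE)
  for (q in seq_len(ncol(prs))) {
    x <- lower_tri(matrices[[prs[1, q]]])
    y <- lower_tri(matrices[[prs[2, q]]])
    out$r[q] <- cor(x, y)
  }
  out$collinear <- abs(out$r) > threshold
  out
}

#' Margin check for a surface around sites
#' @param surface a `resistance_surface` or [raster_grid()]
#' @param sites data frame with `x`, `y`
#' @param margin_m required margin in meters (default 7000)
#' @return TRUE/FALSE
#' @export
check_margin <- function(surface, sites, margin_m = 7000) {
  xmax <- surface$xll + ncol(surface$grid) * surface$cellsize
  ymax <- surface$yll + nrow(surface$grid) * surface$cellsize
  all(sites$x - surface$xll >= margin_m, xmax - sites$x >= margin_m,
      sites$y - surface$yll >= margin_m, ymax - sites$y >= margin_m)
}
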