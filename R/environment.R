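#' Create a nutrient lattice
#'
#' Builds the square lattice of nutrient-bearing cells on which the
#' simulated plants live. Each cell holds a single scalar nutrient stock
#' (grams) that is replenished linearly once per day at rate `r` up to the
#' cap `Rmax`, and drawn down by the photosynthetic demand of its
#' occupants (contest competition, see [serve_consumption()]).
#'
#' Cells are indexed 1..L^2 in column-major order (the same layout as an R
#' `matrix(, L, L)`); `(row, col)` coordinates are 1-based. The adjacency
#' used for seed dispersal is precomputed at construction: the 8-cell Moore
#' neighborhood by default, or the 4-cell von Neumann neighborhood, under
#' either periodic (`torus`) or absorbing (`clipped`) boundaries. Under
#' `torus` boundaries the neighbor list always has full length; on
#' degenerate lattices (L < 3) wrapped neighbors may coincide, which keeps
#' dispersal uniform over the neighborhood offsets.
#'
#' @param L side length of the lattice (cells); the grid has `L^2` cells.
#' @param r daily nutrient replenishment rate (g/day/cell).
#' @param Rmax maximum nutrient stock per cell (g/cell).
#' @param boundary `"torus"` (periodic, default) or `"clipped"`.
#' @param neighborhood `"moore"` (8 cells, default) or `"von_neumann"` (4).
#' @param initial initial stock per cell (g); defaults to `Rmax`.
#' @return An object of class `nutrient_lattice`: a list with fields `L`,
#'   `r`, `Rmax`, `boundary`, `neighborhood`, `stock` (numeric vector of
#'   length `L^2`), `nbr` (neighbor index table, valid entries packed
#'   left), and `n_nbr` (number of valid neighbors per cell).
#' @examples
#' env <- lattice_env(L = 5, r = 1, Rmax = 10)
#' sum(env$stock)  # 5 * 5 * 10
#' @export
lattice_env <- function(L, r, Rmax,
                        boundary = c("torus", "clipped"),
                        neighborhood = c("moore", "von_neumann"),
                        initial = Rmax) {
  boundary <- match.arg(boundary)
  neighborhood <- match.arg(neighborhood)
  if (length(L) != 1L || is.na(L) || L < 1 || L != as.integer(L))
    stop("`L` must be a single integer >= 1")
  if (!is.numeric(r) || length(r) != 1L || r < 0)
    stop("`r` must be a single non-negative number")
  if (!is.numeric(Rmax) || length(Rmax) != 1L || Rmax <= 0)
    stop("`Rmax` must be a single positive number")
  if (initial < 0 || initial > Rmax)
    stop("`initial` stock must lie in [0, Rmax]")
  L <- as.integer(L)
  nb <- build_neighbor_table(L, boundary, neighborhood)
  structure(
    list(L = L, r = r, Rmax = Rmax,
         boundary = boundary, neighborhood = neighborhood,
         stock = rep(as.numeric(initial), L * L),
         nbr = nb$idx, n_nbr = nb$count),
    class = "nutrient_lattice"
  )
}

# Precompute, for every cell, the indices of its adjacent cells.
# Valid neighbors are packed into the leftmost columns so that uniform
# dispersal can index column `ceiling(runif * n_nbr)` directly.
build_neighbor_table <- function(L, boundary, neighborhood) {
  offs <- if (neighborhood == "moore") {
    cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
          dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  } else {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  }
  n <- L * L
  k <- nrow(offs)
  idx <- matrix(NA_integer_, n, k)
  count <- integer(n)
  for (cell in seq_len(n)) {
    row0 <- (cell - 1L) %% L      # 0-based
    col0 <- (cell - 1L) %/% L
    for (j in seq_len(k)) {
      rr <- row0 + offs[j, 1L]
      cc <- col0 + offs[j, 2L]
      if (boundary == "torus") {
        rr <- rr %% L
        cc <- cc %% L
      } else if (rr < 0L || rr >= L || cc < 0L || cc >= L) {
        next
      }
      count[cell] <- count[cell] + 1L
      idx[cell, count[cell]] <- cc * L + rr + 1L
    }
  }
  list(idx = idx, count = count)
}

#' Convert between cell indices and (row, col) coordinates
#'
#' @param env a [lattice_env()] object.
#' @param row,col 1-based coordinates.
#' @param cell 1-based column-major cell index.
#' @return `cell_index()` returns the cell index; `cell_coords()` a
#'   two-column integer matrix of (row, col).
#' @export
cell_index <- function(env, row, col) {
  stopifnot(all(row >= 1L), all(row <= env$L), all(col >= 1L), all(col <= env$L))
  as.integer((col - 1L) * env$L + row)
}

#' @rdname cell_index
#' @export
cell_coords <- function(env, cell) {
  stopifnot(all(cell >= 1L), all(cell <= env$L^2))
  cbind(row = as.integer((cell - 1L) %% env$L + 1L),
        col = as.integer((cell - 1L) %/% env$L + 1L))
}

#' Daily nutrient replenishment
#'
#' Adds `r` grams to every cell's stock, truncating at `Rmax`. Applied once
#' per simulated day, at the start of the day, before any consumption.
#'
#' @param env a [lattice_env()] object.
#' @return The lattice with updated stocks.
#' @export
replenish <- function(env) {
  stopifnot(inherits(env, "nutrient_lattice"))
  env$stock <- pmin(env$stock + env$r, env$Rmax)
  env
}

#' Serve a consumption request (contest competition)
#'
#' Grants `min(demand, stock)` from one cell, the all-or-remainder rule of
#' contest competition: an individual whose photosynthetic demand exceeds
#' the available stock consumes everything that is left.
#'
#' @param env a [lattice_env()] object.
#' @param cell a cell index, or a `(row, col)` pair.
#' @param demand requested amount (g), must be non-negative.
#' @return A list with `granted` (g) and `env` (the lattice after the
#'   withdrawal).
#' @export
serve_consumption <- function(env, cell, demand) {
  stopifnot(inherits(env, "nutrient_lattice"))
  if (length(cell) == 2L) cell <- cell_index(env, cell[1L], cell[2L])
  if (cell < 1L || cell > env$L^2) stop("cell index out of grid")
  if (!is.numeric(demand) || length(demand) != 1L || is.na(demand) || demand < 0)
    stop("`demand` must be a single non-negative number")
  granted <- min(demand, env$stock[cell])
  env$stock[cell] <- env$stock[cell] - granted
  list(granted = granted, env = env)
}

#' Adjacent cells of a lattice cell
#'
#' Returns the coordinates of the cells adjacent to `coords` under the
#' lattice's neighborhood and boundary mode: all 8 (Moore) or 4 (von
#' Neumann) neighbors under `torus` boundaries, only the in-grid ones
#' (3-8) under `clipped` boundaries.
#'
#' @param env a [lattice_env()] object.
#' @param coords a `(row, col)` pair (1-based) or a single cell index.
#' @return A two-column integer matrix of neighbor (row, col) coordinates.
#' @export
neighbors <- function(env, coords) {
  stopifnot(inherits(env, "nutrient_lattice"))
  cell <- if (length(coords) == 2L) {
    if (any(coords < 1L) || any(coords > env$L))
      stop("coordinates out of grid")
    cell_index(env, coords[1L], coords[2L])
  } else {
    if (coords < 1L || coords > env$L^2) stop("cell index out of grid")
    as.integer(coords)
  }
  ids <- env$nbr[cell, seq_len(env$n_nbr[cell])]
  cell_coords(env, ids)
}

#' @export
print.nutrient_lattice <- function(x, ...) {
  cat(sprintf(
    "<nutrient_lattice> %d x %d cells, r = %g g/day, Rmax = %g g/cell\n",
    x$L, x$L, x$r, x$Rmax))
  cat(sprintf("  boundary: %s, neighborhood: %s\n", x$boundary, x$neighborhood))
  cat(sprintf("  total stock: %.2f g (mean %.2f g/cell)\n",
              sum(x$stock), mean(x$stock)))
  invisible(x)
}
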