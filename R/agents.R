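## Lattice tumour-cell agents: circular seeding, Moore neighbourhoods,
## chemotactic migration, delayed proliferation, boundary detection.

.new_agents <- function(row, col, phenotype, clock, mol) {
  structure(list(row = as.integer(row), col = as.integer(col),
                 phenotype = phenotype, clock = as.integer(clock),
                 mol = mol),
            class = "gs_agents")
}

#' Seed a circular tumour at the lattice centre
#'
#' Places one agent at every site whose integer offset (i, j) from the
#' central site satisfies `i^2 + j^2 <= radius^2`. On the 200 x 200 grid the
#' radius-16 closed lattice disc contains exactly 797 sites, the initial
#' cell count of the reference configuration.
#'
#' @param n_side Lattice side length (sites).
#' @param radius Disc radius (sites); must satisfy `2 * radius < n_side`.
#' @return List with elements `agents` (a `gs_agents` set, phenotype
#'   QUIESCENT, zero molecular state) and `occupancy` (logical matrix).
#' @examples
#' length(seed_tumour(200, 16)$agents$row)  # 797
#' @export
seed_tumour <- function(n_side, radius) {
  n_side <- as.integer(n_side)
  radius <- as.integer(radius)
  if (radius < 0) stop("radius must be >= 0")
  if (2L * radius >= n_side)
    stop("radius ", radius, " too large for a ", n_side, "-site lattice")
  centre <- n_side %/% 2L + 1L
  off <- seq.int(-radius, radius)
  grid <- expand.grid(i = off, j = off)
  keep <- grid$i^2 + grid$j^2 <= radius^2
  row <- centre + grid$i[keep]
  col <- centre + grid$j[keep]
  ord <- order(row, col)
  row <- row[ord]; col <- col[ord]
  occ <- matrix(FALSE, n_side, n_side)
  occ[cbind(row, col)] <- TRUE
  agents <- .new_agents(row, col,
                        rep(PHENOTYPE_QUIESCENT, length(row)),
                        rep(0L, length(row)),
                        matrix(0, length(row), 9,
                               dimnames = list(NULL, .gs_species)))
  list(agents = agents, occupancy = occ)
}

#' Moore neighbourhood of a lattice site
#'
#' The eight surrounding sites in a fixed clockwise order starting north,
#' clipped at the lattice edges.
#'
#' @param pos Integer vector `(row, col)`, 1-based.
#' @param n_side Lattice side length.
#' @return Integer matrix with columns `row`, `col`.
#' @export
neighbor_sites <- function(pos, n_side) {
  r <- pos[1]; c <- pos[2]
  if (r < 1 || r > n_side || c < 1 || c > n_side)
    stop("pos outside the lattice")
  ## N, NE, E, SE, S, SW, W, NW
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  nr <- r + dr; nc <- c + dc
  keep <- nr >= 1L & nr <= n_side & nc >= 1L & nc <= n_side
  cbind(row = nr[keep], col = nc[keep])
}

## pick the empty neighbour with maximal glucose; ties broken uniformly at
## random from the session RNG; NULL when no empty neighbour exists
.best_empty_neighbor <- function(world, r, c) {
  nb <- neighbor_sites(c(r, c), world$n_side)
  empty <- !world$occupancy[nb]
  if (!any(empty)) return(NULL)
  nb <- nb[empty, , drop = FALSE]
  g <- world$glucose$values[nb]
  best <- which(g == max(g))
  pick <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
  unname(nb[pick, ])
}

#' Let one agent act on the lattice
#'
#' Migrating agents move to the empty Moore neighbour with maximal glucose
#' (chemotaxis; glucose ties broken uniformly at random; no empty neighbour
#' means the agent stays). Proliferating agents with an expired division
#' clock place a daughter (a copy of the molecular state, clock reset to the
#' world's division delay) on the best empty neighbour and reset their own
#' clock; otherwise the clock counts down. Quiescent agents do nothing.
#' Randomness is drawn from the session RNG.
#'
#' @param world A world state (see [init_world()]).
#' @param index Index of the agent to act.
#' @return The updated world.
#' @export
act <- function(world, index) {
  a <- world$agents
  n <- length(a$row)
  if (index < 1L || index > n) stop("agent index out of range")
  phen <- a$phenotype[index]
  r <- a$row[index]; c <- a$col[index]
  if (!world$occupancy[r, c])
    stop("inconsistent occupancy at (", r, ", ", c, ")")
  if (phen == PHENOTYPE_MIGRATING) {
    dest <- .best_empty_neighbor(world, r, c)
    if (!is.null(dest)) {
      world$occupancy[r, c] <- FALSE
      world$occupancy[dest[1], dest[2]] <- TRUE
      a$row[index] <- dest[1]
      a$col[index] <- dest[2]
    }
  } else if (phen == PHENOTYPE_PROLIFERATING) {
    if (a$clock[index] > 0L) {
      a$clock[index] <- a$clock[index] - 1L
    } else {
      dest <- .best_empty_neighbor(world, r, c)
      if (!is.null(dest)) {
        world$occupancy[dest[1], dest[2]] <- TRUE
        a$row <- c(a$row, dest[1])
        a$col <- c(a$col, dest[2])
        a$phenotype <- c(a$phenotype, phen)
        a$clock <- c(a$clock, world$t_div)
        a$mol <- rbind(a$mol, a$mol[index, , drop = FALSE])
        a$clock[index] <- world$t_div
      }
    }
  }
  world$agents <- a
  world
}

#' Has any cell reached the lattice boundary?
#'
#' @param world A world state.
#' @return TRUE iff an agent occupies the first or last row or column.
#' @export
boundary_reached <- function(world) {
  a <- world$agents
  any(a$row == 1L | a$row == world$n_side |
        a$col == 1L | a$col == world$n_side)
}

#' Check world invariants
#'
#' Verifies that the occupancy grid is consistent with the agent positions
#' and that no site hosts two agents.
#'
#' @param world A world state.
#' @return TRUE invisibly; errors on violation.
#' @export
validate_world <- function(world) {
  a <- world$agents
  idx <- cbind(a$row, a$col)
  if (anyDuplicated(idx))
    stop("exclusion violated: two agents share a site")
  occ <- matrix(FALSE, world$n_side, world$n_side)
  occ[idx] <- TRUE
  if (!identical(occ, world$occupancy))
    stop("occupancy grid inconsistent with agent positions")
  invisible(TRUE)
}
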