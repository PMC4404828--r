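#' Load and validate an arena configuration
#'
#' Reads a keyed YAML arena description (zone geometry, movement adjacency,
#' named zone aggregates) and returns a validated `mcsf_arena` object.  The
#' bundled default, `mcsf_default()`, encodes the ten zones of the
#' multivariate concentric square field: center, central circle (CTRCI),
#' corridors A-C, dark corner room (DCR), hurdle, slope, bridge entrance
#' (BE) and bridge.
#'
#' Coordinates use the arena lower-left corner as origin, x right, y up, in
#' cm.  Rectangles are half-open (`xmin <= x < xmax`), circles open
#' (`dist < radius`), so a point on a shared boundary belongs to the zone
#' listed first in configuration order.
#'
#' @param path Path to a YAML arena configuration file.
#' @return An object of class `mcsf_arena`: a list with elements `name`,
#'   `arena_size` (width, height in cm), `session_duration` (s), `zones`
#'   (list of zone definitions), `adjacency` (two-column character matrix of
#'   unordered zone pairs) and `aggregates` (named list of zone-id vectors).
#' @examples
#' arena <- mcsf_default()
#' zone_ids(arena)
#' locate_zone(c(50, 50), arena)
#' @export
load_arena_config <- function(path) {
  if (!file.exists(path)) stop("arena config file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("arena config parse failure in '", path, "': ", conditionMessage(e))
  })
  arena <- as_arena(raw)
  arena
}

#' @rdname load_arena_config
#' @export
mcsf_default <- function() {
  path <- system.file("extdata", "mcsf_default.yaml", package = "mcsfr",
                      mustWork = TRUE)
  load_arena_config(path)
}

# Build + validate an mcsf_arena from a parsed config list.
as_arena <- function(raw) {
  required <- c("arena_size", "session_duration", "zones")
  missing_keys <- setdiff(required, names(raw))
  if (length(missing_keys)) {
    stop("arena config format error: missing key(s) ",
         paste(missing_keys, collapse = ", "))
  }
  zones <- lapply(raw$zones, normalize_zone)
  adjacency <- do.call(rbind, lapply(raw$adjacency, function(p) {
    if (length(p) != 2L) {
      stop("arena config format error: key 'adjacency' entries must be pairs")
    }
    as.character(p)
  }))
  if (is.null(adjacency)) adjacency <- matrix(character(), ncol = 2)
  aggregates <- lapply(raw$aggregates, as.character)
  arena <- structure(
    list(
      name = if (!is.null(raw$name)) as.character(raw$name) else "arena",
      arena_size = as.numeric(raw$arena_size),
      session_duration = as.numeric(raw$session_duration),
      zones = zones,
      adjacency = adjacency,
      aggregates = aggregates
    ),
    class = "mcsf_arena"
  )
  validate_arena(arena)
  arena
}

normalize_zone <- function(z) {
  if (is.null(z$zone_id)) {
    stop("arena config format error: zone without key 'zone_id'")
  }
  if (is.null(z$shape) || !z$shape %in% c("rect", "circle")) {
    stop("arena config format error: zone '", z$zone_id,
         "' key 'shape' must be 'rect' or 'circle'")
  }
  list(
    zone_id = as.character(z$zone_id),
    display_name = if (!is.null(z$display_name)) z$display_name else z$zone_id,
    shape = z$shape,
    xlim = if (!is.null(z$xlim)) as.numeric(z$xlim) else NULL,
    ylim = if (!is.null(z$ylim)) as.numeric(z$ylim) else NULL,
    center = if (!is.null(z$center)) as.numeric(z$center) else NULL,
    radius = if (!is.null(z$radius)) as.numeric(z$radius) else NULL,
    parent_zone = if (!is.null(z$parent_zone)) as.character(z$parent_zone) else NA_character_,
    role_tags = if (!is.null(z$role_tags)) as.character(z$role_tags) else character(),
    light_lux = if (!is.null(z$light_lux)) as.numeric(z$light_lux) else NULL
  )
}

validate_arena <- function(arena) {
  problems <- character()
  ids <- vapply(arena$zones, `[[`, "", "zone_id")
  if (anyDuplicated(ids)) {
    problems <- c(problems, paste0("duplicate zone_id: ",
                                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (length(arena$arena_size) != 2L || any(!is.finite(arena$arena_size)) ||
      any(arena$arena_size <= 0)) {
    problems <- c(problems, "arena_size must be two positive numbers")
  }
  if (!is.finite(arena$session_duration) || arena$session_duration <= 0) {
    problems <- c(problems, "session_duration must be > 0")
  }
  w <- arena$arena_size[1]; h <- arena$arena_size[2]
  for (z in arena$zones) {
    if (z$shape == "rect") {
      if (is.null(z$xlim) || is.null(z$ylim) || length(z$xlim) != 2 ||
          length(z$ylim) != 2 || z$xlim[1] >= z$xlim[2] || z$ylim[1] >= z$ylim[2]) {
        problems <- c(problems, paste0("zone '", z$zone_id, "': bad rect geometry"))
        next
      }
      if (z$xlim[1] < 0 || z$xlim[2] > w || z$ylim[1] < 0 || z$ylim[2] > h) {
        problems <- c(problems, paste0("zone '", z$zone_id, "': outside arena bounds"))
      }
    } else {
      if (is.null(z$center) || is.null(z$radius) || length(z$center) != 2 ||
          z$radius <= 0) {
        problems <- c(problems, paste0("zone '", z$zone_id, "': bad circle geometry"))
        next
      }
      if (z$center[1] - z$radius < 0 || z$center[1] + z$radius > w ||
          z$center[2] - z$radius < 0 || z$center[2] + z$radius > h) {
        problems <- c(problems, paste0("zone '", z$zone_id, "': outside arena bounds"))
      }
    }
    if (!is.na(z$parent_zone)) {
      if (!z$parent_zone %in% ids) {
        problems <- c(problems, paste0("zone '", z$zone_id,
                                       "': parent_zone '", z$parent_zone, "' not defined"))
      } else {
        parent <- arena$zones[[match(z$parent_zone, ids)]]
        if (!zone_contains_zone(parent, z)) {
          problems <- c(problems, paste0("zone '", z$zone_id,
                                         "' not geometrically contained in parent '",
                                         z$parent_zone, "'"))
        }
      }
    }
    if (all(c("risk", "shelter") %in% z$role_tags)) {
      problems <- c(problems, paste0("zone '", z$zone_id,
                                     "': role_tags cannot include both risk and shelter"))
    }
  }
  if (nrow(arena$adjacency)) {
    bad <- !(arena$adjacency %in% ids)
    if (any(bad)) {
      problems <- c(problems, paste0("adjacency references unknown zone(s): ",
                                     paste(unique(arena$adjacency[bad]), collapse = ", ")))
    }
    if (any(arena$adjacency[, 1] == arena$adjacency[, 2])) {
      problems <- c(problems, "adjacency contains self-pairs")
    }
  }
  for (agg in names(arena$aggregates)) {
    miss <- setdiff(arena$aggregates[[agg]], ids)
    if (length(miss)) {
      problems <- c(problems, paste0("aggregate '", agg, "' references unknown zone(s): ",
                                     paste(miss, collapse = ", ")))
    }
  }
  # every shelter-tagged zone must have exactly one non-shelter neighbour
  # (in the MCSF: corridor A is the only access to the DCR)
  shelter_ids <- ids[vapply(arena$zones, function(z) "shelter" %in% z$role_tags, TRUE)]
  for (sid in shelter_ids) {
    nb <- zone_neighbors(arena, sid)
    nb_nonshelter <- setdiff(nb, shelter_ids)
    if (length(nb_nonshelter) != 1L) {
      problems <- c(problems, paste0("shelter zone '", sid,
                                     "' must have exactly one non-shelter neighbour, has ",
                                     length(nb_nonshelter)))
    }
  }
  if (length(problems)) {
    stop("arena config validation error:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  invisible(arena)
}

# crude containment check (sufficient for rect/circle nesting used here)
zone_contains_zone <- function(parent, child) {
  if (parent$shape == "rect" && child$shape == "circle") {
    child$center[1] - child$radius >= parent$xlim[1] &&
      child$center[1] + child$radius <= parent$xlim[2] &&
      child$center[2] - child$radius >= parent$ylim[1] &&
      child$center[2] + child$radius <= parent$ylim[2]
  } else if (parent$shape == "rect" && child$shape == "rect") {
    child$xlim[1] >= parent$xlim[1] && child$xlim[2] <= parent$xlim[2] &&
      child$ylim[1] >= parent$ylim[1] && child$ylim[2] <= parent$ylim[2]
  } else if (parent$shape == "circle" && child$shape == "circle") {
    sqrt(sum((parent$center - child$center)^2)) + child$radius <= parent$radius
  } else {
    # rect child of circle parent: all four corners inside
    corners <- expand.grid(x = child$xlim, y = child$ylim)
    all(sqrt((corners$x - parent$center[1])^2 +
               (corners$y - parent$center[2])^2) <= parent$radius)
  }
}

#' @export
print.mcsf_arena <- function(x, ...) {
  cat("<mcsf_arena> '", x$name, "': ", x$arena_size[1], " x ", x$arena_size[2],
      " cm, ", length(x$zones), " zones, session ", x$session_duration, " s\n",
      sep = "")
  cat("  zones: ", paste(zone_ids(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Zone identifiers of an arena, in configuration order
#' @param arena An `mcsf_arena`.
#' @return Character vector of zone ids.
#' @export
zone_ids <- function(arena) {
  vapply(arena$zones, `[[`, "", "zone_id")
}

#' Zones adjacent to a zone in the arena movement graph
#' @param arena An `mcsf_arena`.
#' @param zone_id A zone id.
#' @return Character vector of neighbouring zone ids.
#' @export
zone_neighbors <- function(arena, zone_id) {
  adj <- arena$adjacency
  unique(c(adj[adj[, 1] == zone_id, 2], adj[adj[, 2] == zone_id, 1]))
}

#' Map coordinates to arena zones
#'
#' Assigns each point to the deepest (most-nested) zone containing it; a
#' point inside the central circle is reported as `ctrci`, not `center`.
#' Points contained by no zone (including non-finite coordinates) return
#' `"unassigned"`.
#'
#' @param point Numeric vector `c(x, y)` in cm (for `locate_zone`).
#' @param x,y Numeric vectors of coordinates (for `locate_zones`).
#' @param arena An `mcsf_arena`.
#' @return A zone id, or `"unassigned"`.
#' @export
locate_zone <- function(point, arena) {
  locate_zones(point[1], point[2], arena)
}

#' @rdname locate_zone
#' @export
locate_zones <- function(x, y, arena) {
  n <- length(x)
  stopifnot(length(y) == n)
  ids <- zone_ids(arena)
  depth <- vapply(arena$zones, function(z) {
    d <- 0L; p <- z$parent_zone
    while (!is.na(p)) {
      d <- d + 1L
      p <- arena$zones[[match(p, ids)]]$parent_zone
    }
    d
  }, 0L)
  out <- rep("unassigned", n)
  best_depth <- rep(-1L, n)
  ok <- is.finite(x) & is.finite(y)
  for (i in seq_along(arena$zones)) {
    z <- arena$zones[[i]]
    inside <- if (z$shape == "rect") {
      ok & x >= z$xlim[1] & x < z$xlim[2] & y >= z$ylim[1] & y < z$ylim[2]
    } else {
      ok & (x - z$center[1])^2 + (y - z$center[2])^2 < z$radius^2
    }
    # deeper zone wins; equal depth keeps the first-listed zone
    take <- inside & depth[i] > best_depth
    out[take] <- z$zone_id
    best_depth[take] <- depth[i]
  }
  out
}

#' Serialize an arena configuration back to YAML
#'
#' Round-trips with [load_arena_config()]: writing then reloading yields an
#' identical arena object.
#'
#' @param arena An `mcsf_arena`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_arena_config <- function(arena, path) {
  zones <- lapply(arena$zones, function(z) {
    out <- list(zone_id = z$zone_id, display_name = z$display_name,
                shape = z$shape)
    if (z$shape == "rect") {
      out$xlim <- z$xlim; out$ylim <- z$ylim
    } else {
      out$center <- z$center; out$radius <- z$radius
    }
    if (!is.na(z$parent_zone)) out$parent_zone <- z$parent_zone
    if (length(z$role_tags)) out$role_tags <- as.list(z$role_tags)
    if (!is.null(z$light_lux)) out$light_lux <- z$light_lux
    out
  })
  raw <- list(
    format_version = 1L,
    name = arena$name,
    arena_size = arena$arena_size,
    session_duration = arena$session_duration,
    zones = zones,
    adjacency = apply(arena$adjacency, 1, as.list),
    aggregates = arena$aggregates
  )
  yaml::write_yaml(raw, path)
  invisible(path)
}
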