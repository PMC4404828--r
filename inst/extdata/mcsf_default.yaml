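# Default multivariate concentric square field (MCSF) arena configuration.
#
# Coordinates: origin at the arena lower-left corner, x right, y up, units cm.
# All rectangle geometry is half-open: a point belongs to a rectangle when
# xmin <= x < xmax and ymin <= y < ymax; circles are open (dist < radius).
# A point on a shared boundary therefore belongs to the zone listed first.
#
# Published dimensions: outer square 100 x 100 cm, inner central field
# 70 x 70 cm, central circle diameter 22 cm.  The corridor width (15 cm)
# and the rectangles assigned to the dark corner room (DCR), hurdle, slope,
# bridge entrance (BE) and bridge are package ASSUMPTIONS: the source
# apparatus description does not give these dimensions, and elevation is
# ignored (planar overhead-view geometry).
format_version: 1
name: mcsf_default
arena_size: [100, 100]
session_duration: 1800
zones:
  - zone_id: center
    display_name: Center field
    shape: rect
    xlim: [15, 85]
    ylim: [15, 85]
    role_tags: []
    light_lux: [0, 25]
  - zone_id: ctrci
    display_name: Central circle
    shape: circle
    center: [50, 50]
    radius: 11
    parent_zone: center
    role_tags: [risk]
    light_lux: [30, 35]
  - zone_id: corr_a
    display_name: Corridor A
    shape: rect
    xlim: [0, 15]
    ylim: [0, 85]
    role_tags: [corridor]
    light_lux: [0, 20]
  - zone_id: corr_b
    display_name: Corridor B
    shape: rect
    xlim: [15, 85]
    ylim: [0, 15]
    role_tags: [corridor]
    light_lux: [0, 20]
  - zone_id: corr_c
    display_name: Corridor C
    shape: rect
    xlim: [85, 100]
    ylim: [0, 85]
    role_tags: [corridor]
    light_lux: [0, 20]
  - zone_id: dcr
    display_name: Dark corner room
    shape: rect
    xlim: [0, 15]
    ylim: [85, 100]
    role_tags: [shelter]
    light_lux: [0, 1]
  - zone_id: hurdle
    display_name: Hurdle (elevated hole board)
    shape: rect
    xlim: [15, 40]
    ylim: [85, 100]
    role_tags: [transit]
    light_lux: [0, 20]
  - zone_id: slope
    display_name: Slope
    shape: rect
    xlim: [40, 55]
    ylim: [85, 100]
    role_tags: [transit]
  - zone_id: be
    display_name: Bridge entrance
    shape: rect
    xlim: [55, 70]
    ylim: [85, 100]
    role_tags: [transit]
  - zone_id: bridge
    display_name: Bridge
    shape: rect
    xlim: [70, 100]
    ylim: [85, 100]
    role_tags: [risk]
    light_lux: [600, 850]
# Movement graph (doorways/walls), not geometric touching.  Corridor A is
# the only access to the shelter (DCR).
adjacency:
  - [center, ctrci]
  - [center, corr_a]
  - [center, corr_b]
  - [center, corr_c]
  - [center, hurdle]
  - [center, slope]
  - [corr_a, dcr]
  - [corr_a, corr_b]
  - [corr_b, corr_c]
  - [hurdle, slope]
  - [slope, be]
  - [be, bridge]
aggregates:
  total_corr: [corr_a, corr_b, corr_c]
  arena: [center, ctrci, corr_a, corr_b, corr_c, dcr, hurdle, slope, be, bridge]
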