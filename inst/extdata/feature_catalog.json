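{
  "version": "1.0",
  "n_features": 65,
  "features": ["area_mean", "area_sd", "area_median", "perimeter_mean", "perimeter_sd", "perimeter_median", "equivalent_diameter_mean", "equivalent_diameter_sd", "equivalent_diameter_median", "elongation_mean", "elongation_sd", "elongation_median", "eccentricity_mean", "eccentricity_sd", "eccentricity_median", "roundness_mean", "roundness_sd", "roundness_median", "solidity_mean", "solidity_sd", "solidity_median", "intensity_mean_mean", "intensity_mean_sd", "intensity_mean_median", "intensity_median_mean", "intensity_median_sd", "intensity_median_median", "intensity_sd_mean", "intensity_sd_sd", "intensity_sd_median", "intensity_min_mean", "intensity_min_sd", "intensity_min_median", "intensity_max_mean", "intensity_max_sd", "intensity_max_median", "voronoi_cell_area_mean", "voronoi_cell_area_sd", "voronoi_cell_area_median", "voronoi_cell_area_min", "voronoi_cell_area_max", "voronoi_cell_area_disorder", "delaunay_edge_length_mean", "delaunay_edge_length_sd", "delaunay_edge_length_median", "delaunay_edge_length_min", "delaunay_edge_length_max", "delaunay_edge_length_disorder", "mst_edge_length_mean", "mst_edge_length_sd", "mst_edge_length_median", "mst_edge_length_min", "mst_edge_length_max", "mst_edge_length_disorder", "neighbor_count_mean", "neighbor_count_sd", "neighbor_count_median", "neighbor_count_min", "neighbor_count_max", "neighbor_count_disorder", "nucleus_density", "voronoi_bounded_fraction", "mst_total_length", "delaunay_mean_degree", "nn_distance_mean"]
}
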