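#pragma once
#include <Rcpp.h>
#include <map>
#include <string>
#include "geometry.h"

namespace pmc {

inline Shape shape_from_list(Rcpp::List s) {
  Shape sh;
  std::string type = Rcpp::as<std::string>(s["type"]);
  Rcpp::NumericVector cen = s.containsElementNamed("center")
                              ? Rcpp::as<Rcpp::NumericVector>(s["center"])
                              : Rcpp::NumericVector::create(0, 0, 0);
  for (int i = 0; i < 3; ++i) sh.c[i] = cen[i];
  if (type == "cylinder") {
    sh.type = SHAPE_CYLINDER;
    sh.r[0] = sh.r[1] = Rcpp::as<double>(s["radius"]);
    sh.r[2] = Rcpp::as<double>(s["height"]) / 2.0;
  } else if (type == "sphere") {
    sh.type = SHAPE_SPHERE;
    sh.r[0] = sh.r[1] = sh.r[2] = Rcpp::as<double>(s["radius"]);
  } else if (type == "ellipsoid") {
    sh.type = SHAPE_ELLIPSOID;
    Rcpp::NumericVector rr = s["radii"];
    for (int i = 0; i < 3; ++i) sh.r[i] = rr[i];
  } else if (type == "box") {
    sh.type = SHAPE_BOX;
    Rcpp::NumericVector sz = s["size"];
    for (int i = 0; i < 3; ++i) sh.r[i] = sz[i] / 2.0;
  } else if (type == "mesh") {
    sh.type = SHAPE_MESH;
    Rcpp::NumericMatrix V = s["vertices"];
    Rcpp::IntegerMatrix F = s["faces"];
    sh.V.resize(3 * V.nrow());
    for (int i = 0; i < V.nrow(); ++i)
      for (int j = 0; j < 3; ++j) sh.V[3 * i + j] = V(i, j);
    sh.F.resize(3 * F.nrow());
    for (int i = 0; i < F.nrow(); ++i)
      for (int j = 0; j < 3; ++j) sh.F[3 * i + j] = F(i, j) - 1;  // to 0-based
  } else {
    Rcpp::stop("unknown shape type '%s'", type);
  }
  return sh;
}

inline Scene scene_from_list(Rcpp::List sc) {
  Scene scene;
  scene.ambient_n = sc.containsElementNamed("ambient_n")
                      ? Rcpp::as<double>(sc["ambient_n"]) : 1.0;
  Rcpp::List regions = sc["regions"];
  const int K = regions.size();
  std::map<int, int> idx;  // region id -> vector index
  scene.regs.resize(K);
  for (int i = 0; i < K; ++i) {
    Rcpp::List rl = regions[i];
    Region& R = scene.regs[i];
    R.id = Rcpp::as<int>(rl["id"]);
    R.shape = shape_from_list(rl["shape"]);
    R.mua = Rcpp::as<double>(rl["mu_a"]);
    R.mus = Rcpp::as<double>(rl["mu_s"]);
    R.g = Rcpp::as<double>(rl["g"]);
    R.n = Rcpp::as<double>(rl["n"]);
    idx[R.id] = i;
  }
  int root = -1;
  for (int i = 0; i < K; ++i) {
    Rcpp::List rl = regions[i];
    const int pid = Rcpp::as<int>(rl["parent"]);
    if (pid == 0) {
      if (root >= 0) Rcpp::stop("scene has more than one root region");
      scene.regs[i].parent = -1;
      root = i;
    } else {
      auto it = idx.find(pid);
      if (it == idx.end()) Rcpp::stop("region %d: unknown parent id %d",
                                      scene.regs[i].id, pid);
      scene.regs[i].parent = it->second;
      scene.regs[it->second].children.push_back(i);
    }
  }
  if (root < 0) Rcpp::stop("scene has no root region (parent = 0)");
  scene.root = root;
  return scene;
}

} // namespace pmc
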