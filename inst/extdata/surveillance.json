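{
  "strategy": "surveillance",
  "root": {
    "type": "chance",
    "branches": [
      {
        "p": {
          "param": "pLowRisk"
        },
        "child": {
          "type": "chance",
          "branches": [
            {
              "p": {
                "param": "pRelapseLowrisk"
              },
              "child": {
                "type": "chance",
                "branches": [
                  {
                    "p": {
                      "param": "pRelapsePostSalvChemo"
                    },
                    "child": {
                      "type": "terminal",
                      "payoff": {
                        "sum": [
                          {
                            "param": "nSalvageCycles"
                          },
                          {
                            "product": [
                              {
                                "param": "nSecondLineCycles"
                              },
                              {
                                "param": "tSecondChemo"
                              }
                            ]
                          }
                        ]
                      }
                    }
                  },
                  {
                    "p": {
                      "complement": {
                        "param": "pRelapsePostSalvChemo"
                      }
                    },
                    "child": {
                      "type": "terminal",
                      "payoff": {
                        "param": "nSalvageCycles"
                      }
                    }
                  }
                ]
              }
            },
            {
              "p": {
                "complement": {
                  "param": "pRelapseLowrisk"
                }
              },
              "child": {
                "type": "terminal",
                "payoff": 0
              }
            }
          ]
        }
      },
      {
        "p": {
          "complement": {
            "param": "pLowRisk"
          }
        },
        "child": {
          "type": "chance",
          "branches": [
            {
              "p": {
                "param": "pRelapseHighrisk"
              },
              "child": {
                "type": "chance",
                "branches": [
                  {
                    "p": {
                      "param": "pRelapsePostSalvChemo"
                    },
                    "child": {
                      "type": "terminal",
                      "payoff": {
                        "sum": [
                          {
                            "param": "nSalvageCycles"
                          },
                          {
                            "product": [
                              {
                                "param": "nSecondLineCycles"
                              },
                              {
                                "param": "tSecondChemo"
                              }
                            ]
                          }
                        ]
                      }
                    }
                  },
                  {
                    "p": {
                      "complement": {
                        "param": "pRelapsePostSalvChemo"
                      }
                    },
                    "child": {
                      "type": "terminal",
                      "payoff": {
                        "param": "nSalvageCycles"
                      }
                    }
                  }
                ]
              }
            },
            {
              "p": {
                "complement": {
                  "param": "pRelapseHighrisk"
                }
              },
              "child": {
                "type": "terminal",
                "payoff": 0
              }
            }
          ]
        }
      }
    ]
  }
}
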